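# Synthetic truth/mapping used by the constructed-case tests below.
toy_peptides <- function() {
  data.frame(
    peptide_id = c("p1", "p2", "p3"),
    length = c(31L, 31L, 21L),
    source_family_id = c("F1", "F2", NA),
    source_protein_id = c("A1", "B1", "H1"),
    stringsAsFactors = FALSE)
}

toy_proteins <- function() {
  data.frame(
    protein_id = c("A1", "A2", "B1", "B2", "H1", "H2"),
    family_id = c("F1", "F1", "F2", "F2", NA, NA),
    stringsAsFactors = FALSE)
}

test_that("classify_hits labels parental, self and coverage correctly", {
  h <- manual_hits(data.frame(
    qseqid = c("p1", "p1", "p1", "p2", "p3"),
    sseqid = c("A1", "A2", "B1", "H2", "A1"),
    length = c(31L, 28L, 20L, 31L, 14L),
    bitscore = c(60, 55, 30, 25, 26)))
  cl <- classify_hits(h, toy_peptides(), toy_proteins())
  expect_s3_class(cl, "ko_classified")
  expect_identical(cl$parental, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(cl$is_self, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(cl$subject_family_id, c("F1", "F1", "F2", NA, "F1"))
  expect_equal(cl$coverage,
               100 * c(31, 28, 20, 31, 14) / c(31, 31, 31, 31, 21))
  # Unknown query / subject ids are rejected with the offending id named.
  bad_q <- manual_hits(data.frame(qseqid = "zz", sseqid = "A1"))
  expect_error(classify_hits(bad_q, toy_peptides(), toy_proteins()), "zz")
  bad_s <- manual_hits(data.frame(qseqid = "p1", sseqid = "XX"))
  expect_error(classify_hits(bad_s, toy_peptides(), toy_proteins()), "XX")
})

test_that("behavior_table counts, percentages and best hits are exact", {
  h <- manual_hits(data.frame(
    qseqid = c("p1", "p1", "p1", "p2", "p3"),
    sseqid = c("A1", "A2", "B1", "H2", "A1"),
    bitscore = c(60, 55, 30, 25, 26)))
  cl <- classify_hits(h, toy_peptides(), toy_proteins())
  # Add a peptide with zero hits so the denominator is exercised.
  peps <- rbind(toy_peptides(),
                data.frame(peptide_id = "p4", length = 31L,
                           source_family_id = "F1",
                           source_protein_id = "A2"))
  tab <- behavior_table(cl, peps)  # self-hit p1->A1 excluded
  expect_identical(tab$peptide_length, c(21L, 31L))
  r31 <- tab[tab$peptide_length == 31L, ]
  expect_equal(r31$total_peptides, 3L)
  expect_equal(r31$aligned, 2L)          # p1 and p2; p4 has no hits
  expect_equal(r31$fraction_aligned, 66.7)
  expect_equal(r31$total_hits, 3L)       # p1->A2, p1->B1, p2->H2
  expect_equal(r31$hits_parental, 1L)
  expect_equal(r31$hits_nonparental, 2L)
  expect_equal(r31$hits_parental + r31$hits_nonparental, r31$total_hits)
  # Best hits: p1's best surviving hit is A2 (parental), p2's is H2.
  expect_equal(r31$besthits_parental, 1L)
  expect_equal(r31$besthits_nonparental, 1L)
  r21 <- tab[tab$peptide_length == 21L, ]
  expect_equal(r21$hits_nonparental, 1L) # unlabeled source: non-parental
  # include_self restores the self-hit and flips p1's best hit to A1.
  tab_s <- behavior_table(cl, peps, include_self = TRUE)
  expect_equal(tab_s[tab_s$peptide_length == 31L, ]$total_hits, 4L)
})

test_that("size-identity trend reports per-family medians and rho", {
  h <- manual_hits(data.frame(
    qseqid = c("p1", "p1", "p2"),
    sseqid = c("A1", "A2", "B2"),   # p1->A1 is a self-hit (excluded)
    pident = c(100, 80, 60),
    bitscore = c(60, 55, 30)))
  cl <- classify_hits(h, toy_peptides(), toy_proteins())
  catalog <- data.frame(family_id = c("F1", "F2", "F3"),
                        n_members = c(2L, 1L, 5L))
  tr <- ko_size_identity_trend(cl, catalog)   # self-hit excluded
  expect_identical(tr$table$family_id, c("F1", "F2"))
  expect_equal(tr$table$median_identity, c(80, 60))
  expect_equal(tr$table$family_size, c(2L, 1L))
  expect_equal(tr$n_families_without_parental_hits, 1L)
  expect_true(is.na(tr$spearman_rho))  # <3 families
  # No parental hits at all -> empty table, NA rho.
  none <- cl[!cl$parental, , drop = FALSE]
  tr0 <- ko_size_identity_trend(none, catalog)
  expect_equal(nrow(tr0$table), 0L)
  expect_equal(tr0$n_families_without_parental_hits, 3L)
})

test_that("ec_similarity computes hierarchical agreement fractions", {
  # Catalog with EC labels engineered for known match depths.
  uni <- list(proteins = toy_proteins(),
              family_catalog = data.frame(
                family_id = c("F1", "F2", "F3"),
                n_members = c(2L, 1L, 1L),
                ec = c("1.2.3.4", "1.2.9.9", "2.1.1.1"),
                stringsAsFactors = FALSE))
  # Non-parental cross-family hits: F1 query -> F2 subject (depth 2),
  # F2 query -> F1 subject (depth 2). Plus one to an unlabeled subject
  # (excluded: no EC).
  h <- manual_hits(data.frame(qseqid = c("p1", "p2", "p2"),
                              sseqid = c("B1", "A2", "H1")))
  cl <- classify_hits(h, toy_peptides(), uni$proteins)
  ec <- ec_similarity(cl, uni)
  expect_equal(ec$n_comparisons, 2L)
  expect_equal(unname(ec$fractions), c(1, 1, 0, 0))
  # Explicitly-empty result when nothing is comparable.
  ec0 <- ec_similarity(cl[cl$sseqid == "H1", , drop = FALSE], uni)
  expect_equal(ec0$n_comparisons, 0L)
  expect_true(all(is.na(ec0$fractions)))
  expect_output(print(ec0), "no eligible")
})

test_that("roc_grid covers the grid, is monotone and validates classes", {
  set.seed(31)
  n <- 4000
  cl <- data.frame(
    parental = rep(c(TRUE, FALSE), each = n / 2),
    pident = c(rnorm(n / 2, 80, 10), rnorm(n / 2, 50, 10)),
    coverage = c(rnorm(n / 2, 90, 8), rnorm(n / 2, 60, 15)),
    is_self = FALSE)
  g <- roc_grid(cl, n_alignments = 3000L, seed = 7L)
  expect_equal(nrow(g), 4 * 6)
  expect_true(all(g$n_alignments == 3000L))
  expect_true(all(g$tpr >= 0 & g$tpr <= 1 & g$fpr >= 0 & g$fpr <= 1))
  # Raising either threshold never raises TPR or FPR.
  for (metric in c("tpr", "fpr")) {
    by_cov <- tapply(g[[metric]], g$identity_min,
                     function(v) all(diff(v) <= 0))
    expect_true(all(by_cov))
    gi <- g[order(g$coverage_min, g$identity_min), ]
    by_id <- tapply(gi[[metric]], gi$coverage_min,
                    function(v) all(diff(v) <= 0))
    expect_true(all(by_id))
  }
  # Determinism and class validation.
  expect_identical(g, roc_grid(cl, n_alignments = 3000L, seed = 7L))
  expect_error(roc_grid(cl[cl$parental, ], seed = 1L), "no non-parental")
  expect_error(roc_grid(cl[!cl$parental, ], seed = 1L), "no parental")
})

test_that("length ANOVA: null data large p, planted effect small p", {
  set.seed(99)
  lens <- c(21L, 31L, 41L)
  make_cl <- function(shift_by_length) {
    do.call(rbind, lapply(seq_along(lens), function(i) {
      data.frame(
        peptide_length = lens[i],
        parental = rep(c(TRUE, FALSE), each = 300),
        pident = c(rnorm(300, 80 + shift_by_length * (i - 1) * 4, 6),
                   rnorm(300, 55, 6)))
    }))
  }
  cl_null <- make_cl(0)
  null_fit <- length_effect_anova(cl_null, n_per_length = 200L,
                                  iterations = 30L, seed = 3L)
  expect_gt(null_fit$mean_p, 0.05)
  alt_fit <- length_effect_anova(make_cl(1), n_per_length = 200L,
                                 iterations = 30L, seed = 3L)
  expect_lt(alt_fit$mean_p, 1e-6)
  # Deterministic under the same seed; insufficient data is an error.
  again <- length_effect_anova(cl_null, n_per_length = 200L,
                               iterations = 30L, seed = 3L)
  expect_identical(null_fit$p_values, again$p_values)
  expect_error(length_effect_anova(cl_null, n_per_length = 301L,
                                   iterations = 2L, seed = 1L),
               "fewer than")
})
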