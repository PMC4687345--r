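toy_universe_map <- function() {
  list(proteins = data.frame(
         protein_id = c("A1", "A2", "B1", "C1", "H1"),
         family_id = c("FA", "FA", "FB", "FC", NA),
         stringsAsFactors = FALSE),
       family_catalog = data.frame(
         family_id = c("FA", "FB", "FC"),
         n_members = c(2L, 1L, 1L),
         stringsAsFactors = FALSE))
}

test_that("peptide weights: counts, 1/N and best-hit identity", {
  h <- manual_hits(data.frame(
    qseqid = c("p1", "p1", "p1", "p2"),
    sseqid = c("A1", "A2", "B1", "C1"),
    pident = c(70, 95, 60, 88),
    bitscore = c(40, 62, 35, 50)))
  w <- peptide_weights(h)
  expect_identical(w$peptide_id, c("p1", "p2"))
  expect_identical(w$n_hits, c(3L, 1L))
  expect_equal(w$weight, c(1 / 3, 1))
  expect_equal(w$best_hit_identity, c(95, 88))  # from the max-bitscore hit
})

test_that("PER_HIT vs PER_FAMILY allocation on the worked example", {
  # One peptide, 3 hits: two into family FA, one into FB.
  h <- manual_hits(data.frame(qseqid = "p1",
                              sseqid = c("A1", "A2", "B1"),
                              bitscore = c(60, 55, 30)))
  w <- peptide_weights(h)
  u <- toy_universe_map()
  per_hit <- weighted_abundance(h, w, u, "PER_HIT")
  expect_identical(per_hit$family_id, c("FA", "FB", "FC"))
  expect_equal(per_hit$weighted_count, c(2 / 3, 1 / 3, 0))
  expect_equal(per_hit$n_peptides, c(1L, 1L, 0L))
  per_fam <- weighted_abundance(h, w, u, "PER_FAMILY")
  expect_equal(per_fam$weighted_count, c(1 / 3, 1 / 3, 0))
  # Hits into unlabeled subjects go to the NONFAMILY bucket.
  h2 <- manual_hits(data.frame(qseqid = "p1",
                               sseqid = c("A1", "H1"),
                               bitscore = c(60, 30)))
  w2 <- peptide_weights(h2)
  ab2 <- weighted_abundance(h2, w2, u)
  expect_equal(attr(ab2, "nonfamily"), 0.5)
  # Unknown subject ids are an error.
  h3 <- manual_hits(data.frame(qseqid = "p1", sseqid = "ZZ"))
  expect_error(weighted_abundance(h3, peptide_weights(h3), u), "ZZ")
})

test_that("PER_HIT mass is conserved on real search output", {
  u <- mid_universe()
  p <- sample_type3(u, seed = 11L)
  h <- search_hits(p, u, actual_scoring())
  w <- peptide_weights(h)
  ab <- weighted_abundance(h, w, u)
  expect_equal(sum(ab$weighted_count) + attr(ab, "nonfamily"),
               nrow(w), tolerance = 1e-6)
  # PER_FAMILY total mass never exceeds PER_HIT total mass.
  abf <- weighted_abundance(h, w, u, "PER_FAMILY")
  expect_lte(sum(abf$weighted_count) + attr(abf, "nonfamily"),
             sum(ab$weighted_count) + attr(ab, "nonfamily") + 1e-9)
})

test_that("filter implements ALL/ANY semantics with a full report", {
  w <- structure(data.frame(
    peptide_id = c("p1", "p2", "p3", "p4"),
    n_hits = c(3L, 80L, 3L, 80L),
    weight = 1 / c(3, 80, 3, 80),
    best_hit_identity = c(40, 40, 90, 90),
    stringsAsFactors = FALSE), class = c("ko_weights", "data.frame"))
  h <- manual_hits(data.frame(qseqid = c("p1", "p2", "p3", "p4"),
                              sseqid = "A1"))
  all_f <- apply_filter(h, w, min_hits = 50L, min_best_identity = 55)
  expect_identical(all_f$report$peptide_id, "p1")   # sparse AND low-id
  expect_true(all_f$report$low_hit_count &&
                all_f$report$low_best_identity)
  expect_setequal(all_f$weights$peptide_id, c("p2", "p3", "p4"))
  expect_setequal(unique(all_f$hits$qseqid), c("p2", "p3", "p4"))
  any_f <- apply_filter(h, w, 50L, 55, combine = "ANY")
  expect_setequal(any_f$report$peptide_id, c("p1", "p2", "p3"))
  expect_error(apply_filter(h, w, min_best_identity = 150), "min_best")
  expect_error(apply_filter(h, w, min_hits = 0L), "min_hits")
})

test_that("deviation stats use the catalog union with zero imputation", {
  mk <- function(ids, vals)
    structure(data.frame(family_id = ids, weighted_count = vals,
                         n_peptides = rep(0L, length(ids))),
              class = c("ko_abundance", "data.frame"),
              nonfamily = 0, allocation = "PER_HIT", n_peptides_used = 0L)
  d <- deviation_stats(mk(c("A", "B"), c(4, 1)), mk(c("B", "C"), c(3, 5)))
  expect_equal(d$n_families, 3L)
  expect_equal(sort(d$table$abs_dev), c(2, 4, 5))
  expect_equal(d$mean_abs_dev, mean(c(4, 2, 5)))
  expect_error(deviation_stats(mk(character(0), numeric(0)),
                               mk(character(0), numeric(0))), "empty")
})

test_that("fold_correction matches the worked example", {
  f <- fold_correction(114.57, 23.6, 9.49)
  expect_equal(round(f$inflation_fold, 2), 12.07)
  expect_equal(round(f$correction_fold, 2), 9.59)
  expect_error(fold_correction(1, 1, 0), "positive")
})

test_that("abundance profiles round-trip through the TSV format", {
  u <- toy_universe_map()
  h <- manual_hits(data.frame(qseqid = "p1",
                              sseqid = c("A1", "H1"),
                              bitscore = c(60, 30)))
  ab <- weighted_abundance(h, peptide_weights(h), u)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(ab, f)
  ab2 <- read_abundance(f)
  expect_equal(as.data.frame(ab2), as.data.frame(ab),
               ignore_attr = TRUE)
  expect_equal(attr(ab2, "nonfamily"), attr(ab, "nonfamily"))
  expect_identical(attr(ab2, "allocation"), attr(ab, "allocation"))
  expect_identical(attr(ab2, "n_peptides_used"),
                   attr(ab, "n_peptides_used"))
})

test_that("composite experiment structure and filter arithmetic hold", {
  u <- mid_universe()
  p3 <- sample_type3(u, seed = 12L)
  h3 <- search_hits(p3, u, actual_scoring())
  # A small "unknown" set: peptides from hypothetical proteins.
  hyp <- hypothetical_proteins(u)
  p2 <- sample_type2(hyp, 31L, per_protein = 2L, seed = 13L)
  h2 <- search_hits(p2, u, actual_scoring())
  cx <- composite_experiment(u, 30L, h3, p3, h2, seed = 5L)
  expect_s3_class(cx, "ko_composite")
  expect_length(cx$subset, 30L)
  expect_true(all(cx$subset %in% u$family_catalog$family_id))
  # Truth counts only subset peptides; profiles span the full catalog.
  expect_equal(sum(cx$truth$weighted_count), cx$n_type3_peptides)
  expect_true(all(cx$truth$weighted_count[
    !cx$truth$family_id %in% cx$subset] == 0))
  for (pr in cx$profiles)
    expect_identical(pr$family_id, u$family_catalog$family_id)
  # Unfiltered deviation is at least the baseline's and the filter
  # can only move the composite toward (not past) the baseline data.
  devs <- vapply(cx$deviations, function(d) d$mean_abs_dev, 0)
  expect_gte(devs[["unfiltered"]], devs[["baseline"]])
  expect_lte(devs[["filtered"]], devs[["unfiltered"]])
  expect_equal(cx$folds$correction_fold,
               (devs[["unfiltered"]] - devs[["filtered"]]) /
                 devs[["baseline"]])
  # Determinism of the subset draw.
  cx2 <- composite_experiment(u, 30L, h3, p3, h2, seed = 5L)
  expect_identical(cx$subset, cx2$subset)
  expect_error(composite_experiment(u, 10000L, h3, p3, h2), "exceeds")
})
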