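test_that("universe generation is deterministic and validated", {
  cfg <- universe_config(n_families = 8L, members_per_family = c(3L, 5L),
                         n_hypothetical = 10L, seed = 11L)
  u1 <- build_universe(cfg)
  u2 <- build_universe(cfg)
  expect_identical(u1$proteins, u2$proteins)
  expect_identical(u1$family_catalog, u2$family_catalog)
  u3 <- build_universe(universe_config(n_families = 8L,
                                       members_per_family = c(3L, 5L),
                                       n_hypothetical = 10L, seed = 12L))
  expect_false(identical(u1$proteins$sequence, u3$proteins$sequence))

  expect_error(universe_config(n_families = 0L), "n_families")
  expect_error(universe_config(members_per_family = c(10L, 5L)),
               "members_per_family")
  expect_error(universe_config(within_family_sub_rate = 0.3,
                               cross_family_sub_rate = 0.2),
               "cross_family_sub_rate")
  # Proteins too short for the longest supported peptide are rejected.
  expect_error(build_universe(universe_config(protein_length = c(60L, 100L))),
               "support peptides")
  expect_silent(suppressMessages(build_universe(universe_config(
    n_families = 3L, members_per_family = c(2L, 3L),
    protein_length = c(60L, 100L), n_hypothetical = 0L,
    min_peptide_support = 31L, seed = 3L))))
})

test_that("universe structure matches its configuration", {
  u <- tiny_universe()
  cfg <- u$config
  fam <- family_proteins(u)
  hyp <- hypothetical_proteins(u)
  expect_equal(nrow(u$family_catalog), cfg$n_families)
  expect_equal(nrow(hyp), cfg$n_hypothetical)
  sizes <- table(fam$family_id)
  expect_true(all(sizes >= cfg$members_per_family[1] &
                    sizes <= cfg$members_per_family[2]))
  expect_true(all(nchar(fam$sequence) >= cfg$protein_length[1]))
  expect_true(all(is.na(hyp$family_id)))
  expect_true(all(is.na(hyp$ec)))
  expect_false(any(is.na(fam$ec)))
  # EC labels have four levels.
  expect_true(all(lengths(strsplit(u$family_catalog$ec, ".",
                                   fixed = TRUE)) == 4L))
})

test_that("family members are near the ancestor, cross-family pairs are not", {
  u <- tiny_universe()
  fam <- family_proteins(u)
  sc <- scoring_params()
  fams <- split(fam, fam$family_id)
  f1 <- fams[[1]]; f2 <- fams[[2]]
  within <- local_align(substr(f1$sequence[1], 1, 80), f1$sequence[2], sc)
  expect_gt(within$pct_identity, 80)
  # Unrelated families: no long high-identity alignment.
  cross <- local_align(substr(f1$sequence[1], 1, 80), f2$sequence[1], sc)
  if (cross$found && cross$aln_length > 40)
    expect_lt(cross$pct_identity, 70)
})

test_that("hypothetical composition tracks the family proteins within 2%", {
  u <- mid_universe()
  split_freq <- function(x) {
    v <- strsplit(paste(x, collapse = ""), "")[[1]]
    tabulate(match(v, AA20_T), 20L) / length(v)
  }
  f <- split_freq(family_proteins(u)$sequence)
  h <- split_freq(hypothetical_proteins(u)$sequence)
  expect_true(all(abs(f - h) < 0.02))
})

test_that("families sharing a pool domain share EC prefixes", {
  # Sharing-heavy configuration so the EC structure is exercised.
  u <- build_universe(universe_config(
    n_families = 20L, members_per_family = c(2L, 4L),
    domain_share_prob = 0.6, cross_family_sub_rate = 0.25,
    n_domains = 6L, n_hypothetical = 0L, seed = 77L))
  shared <- u$domain_map[nchar(u$domain_map$families) > 6, , drop = FALSE]
  expect_gt(nrow(shared), 0)
  # Invariants: families sharing a pool domain always agree at EC level
  # 1 (same component), and at least one sharing pair agrees at levels
  # 1-3 (a component root and its direct neighbor).
  found3 <- FALSE
  for (i in seq_len(nrow(shared))) {
    fams <- strsplit(shared$families[i], ";", fixed = TRUE)[[1]]
    if (length(fams) < 2) next
    ecs <- u$family_catalog$ec[match(fams, u$family_catalog$family_id)]
    parts <- strsplit(ecs, ".", fixed = TRUE)
    lvl1 <- vapply(parts, `[`, "", 1)
    expect_true(all(lvl1 == lvl1[1]))
    pre3 <- vapply(parts, function(p) paste(p[1:3], collapse = "."), "")
    if (anyDuplicated(pre3)) found3 <- TRUE
  }
  expect_true(found3)
})

test_that("universe round-trips through the directory format", {
  u <- tiny_universe()
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "proteins.faa", "mapping.tsv", "domains.tsv",
    "family_domains.tsv", "config.txt")))))
  u2 <- read_universe(dir)
  expect_identical(u$proteins, u2$proteins)
  expect_identical(u$family_catalog, u2$family_catalog)
  expect_identical(unclass(u$config), unclass(u2$config))
  # Rewriting is byte-identical.
  dir2 <- withr::local_tempdir()
  write_universe(u2, dir2)
  for (f in c("proteins.faa", "mapping.tsv", "config.txt"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("malformed mapping files raise line-numbered errors", {
  dir <- withr::local_tempdir()
  u <- tiny_universe()
  write_universe(u, dir)
  bad <- readLines(file.path(dir, "mapping.tsv"))
  bad[3] <- "only_one_field"
  writeLines(bad, file.path(dir, "mapping.tsv"))
  expect_error(read_universe(dir), "line 3")
})
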