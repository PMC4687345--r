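test_that("scoring_params validates its inputs", {
  sc <- scoring_params()
  expect_s3_class(sc, "ko_scoring")
  expect_identical(sc$gap_open, 11L)
  expect_identical(sc$gap_extend, 1L)
  expect_true(grepl("^ARNDCQEGHILKMFPSTWYV", sc$alphabet))

  expect_error(scoring_params(gap_open = 1L, gap_extend = 5L), "gap_open")
  expect_error(scoring_params(lambda = -1), "lambda")
  expect_error(scoring_params(k = 0), "k must be")
  bad <- matrix(1:4, 2, 2, dimnames = list(c("A", "C"), c("A", "G")))
  expect_error(scoring_params(matrix = bad), "dimnames")
  asym <- matrix(c(1, 2, 3, 1), 2, 2,
                 dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(scoring_params(matrix = asym), "symmetric")
})

test_that("local_align matches hand-computed small cases", {
  sc <- scoring_params()
  # Exact match: ACDEFG vs itself. BLOSUM62 diagonal:
  # A=4 C=9 D=6 E=5 F=6 G=6 -> 36.
  a <- local_align("ACDEFG", "ACDEFG", sc)
  expect_equal(a$score, 36)
  expect_equal(a$matches, 6)
  expect_equal(a$mismatches, 0)
  expect_equal(a$gap_opens, 0)
  expect_equal(a$pct_identity, 100)
  expect_equal(c(a$q_start, a$q_end, a$s_start, a$s_end), c(1, 6, 1, 6))

  # One substitution (E->K at position 4): K/E off-diagonal is 1,
  # so 4+9+6+1+6+6 = 32.
  b <- local_align("ACDEFG", "ACDKFG", sc)
  expect_equal(b$score, 32)
  expect_equal(b$matches, 5)
  expect_equal(b$mismatches, 1)

  # Empty / unknown handling.
  expect_error(local_align("", "ACD", sc), "non-empty")
  expect_error(local_align("ACBDX1", "ACD", sc), "position")
  expect_silent(local_align("AC1D", "ACD", sc, unknown = "zero"))
})

test_that("gap penalties follow the open + g*extend convention", {
  sc <- scoring_params()
  # Query = subject with a 2-residue deletion; flanks score highly enough
  # that bridging the gap beats splitting.
  s <- "MKWVTFISLLFLFSSAYSRGVFRR"
  q <- paste0(substr(s, 1, 10), substr(s, 13, 24))
  a <- local_align(q, s, sc)
  full <- local_align(s, s, sc)$score
  drop <- local_align(substr(s, 11, 12), substr(s, 11, 12), sc)$score
  expect_equal(a$gap_opens, 1)
  expect_equal(a$aln_length, 24)
  expect_equal(a$score, full - drop - (sc$gap_open + 2 * sc$gap_extend))
})

test_that("alignment is deterministic under ties", {
  sc <- scoring_params()
  a1 <- local_align("AAAA", "AAAAAAA", sc)
  a2 <- local_align("AAAA", "AAAAAAA", sc)
  expect_identical(a1, a2)
  expect_equal(a1$s_start, 1)  # earliest subject position preferred
})

test_that("evalue reproduces the published formula and example", {
  sc <- scoring_params()
  # 31-mer, 1e6 residues, S = 40 -> ~29.2 at lambda=.267, K=.041.
  expect_equal(evalue(40, 31, 1e6, sc), 29.2, tolerance = 0.01)
  expect_equal(evalue(0, 10, 10, sc), sc$k * 100)
  # Monotone decreasing in score.
  e <- evalue(seq(10, 100, 10), 31, 1e6, sc)
  expect_true(all(diff(e) < 0))
  expect_error(evalue(10, 0, 5, sc), "m and n")
})

test_that("bitscore is the standard transform", {
  sc <- scoring_params()
  expect_equal(bitscore(0, sc), -log(sc$k) / log(2))
  expect_equal(bitscore(100, sc), (sc$lambda * 100 - log(sc$k)) / log(2))
})

test_that("min_significant_score inverts the e-value at the cutoff", {
  sc <- scoring_params()
  for (m in c(11, 31, 81)) {
    for (n in c(1e5, 6e5, 1e8)) {
      s <- pepko:::min_significant_score(m, n, 10, sc)
      expect_lte(evalue(s, m, n, sc), 10)
      expect_gt(evalue(s - 1, m, n, sc), 10)
    }
  }
  expect_identical(pepko:::min_significant_score(5, 5, 1e6, sc), 1L)
})
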