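test_that("search output is ordered, significant and well-formed", {
  u <- mid_universe()
  p <- sample_type1(u, 31L, per_family = 2L, seed = 4L)
  h <- search_hits(p, u, actual_scoring(), evalue_max = 1)
  expect_s3_class(h, "ko_hits")
  expect_identical(names(h),
                   c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore"))
  expect_true(all(h$evalue <= 1))
  expect_equal(attr(h, "evalue_max"), 1)
  # One best alignment per (query, subject) pair.
  expect_equal(anyDuplicated(paste(h$qseqid, h$sseqid)), 0L)
  # Ordering: query id, then ascending e-value, then descending bit score.
  o <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid, method = "radix")
  expect_identical(o, seq_len(nrow(h)))
  # Coordinates are 1-based, forward and within the sequences.
  expect_true(all(h$qstart >= 1 & h$qstart <= h$qend & h$qend <= 31))
  slen <- nchar(u$proteins$sequence[match(h$sseqid,
                                          u$proteins$protein_id)])
  expect_true(all(h$sstart >= 1 & h$sstart <= h$send & h$send <= slen))
  # Tightening the cutoff only removes rows, never rescores them.
  h01 <- search_hits(p, u, actual_scoring(), evalue_max = 0.1)
  key <- function(x) paste(x$qseqid, x$sseqid)
  expect_true(all(key(h01) %in% key(h)))
  expect_equal(as.data.frame(h01),
               {d <- as.data.frame(h[h$evalue <= 0.1, ]);
                rownames(d) <- NULL; d}, ignore_attr = TRUE)
})

test_that("every peptide aligns to its own source protein", {
  u <- tiny_universe()
  p <- sample_type1(u, 31L, per_family = 2L, seed = 6L)
  h <- search_hits(p, u, actual_scoring(), evalue_max = 10)
  self <- h[h$sseqid == p$source_protein_id[match(h$qseqid,
                                                  p$peptide_id)], ]
  expect_setequal(self$qseqid, p$peptide_id)
  expect_true(all(self$pident == 100))
  expect_true(all(self$length == 31L & self$mismatch == 0L &
                    self$gapopen == 0L))
  expect_true(all(self$qstart == 1L & self$qend == 31L))
  expect_identical(self$sstart,
                   p$start[match(self$qseqid, p$peptide_id)] + 1L)
})

test_that("exclude_self removes exactly the source-protein alignments", {
  u <- tiny_universe()
  p <- sample_type1(u, 31L, per_family = 2L, seed = 6L)
  all_h <- search_hits(p, u, actual_scoring())
  noself <- search_hits(p, u, actual_scoring(), exclude_self = TRUE)
  expect_true(attr(noself, "self_hits_excluded"))
  src <- p$source_protein_id[match(noself$qseqid, p$peptide_id)]
  expect_false(any(noself$sseqid == src))
  is_self <- all_h$sseqid ==
    p$source_protein_id[match(all_h$qseqid, p$peptide_id)]
  expect_equal(as.data.frame(noself),
               {d <- as.data.frame(all_h[!is_self, ]);
                rownames(d) <- NULL; d}, ignore_attr = TRUE)
})

test_that("search is deterministic and validates inputs", {
  u <- tiny_universe()
  p <- sample_type1(u, 21L, per_family = 1L, seed = 2L)
  h1 <- search_hits(p, u, actual_scoring())
  h2 <- search_hits(p, u, actual_scoring())
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_error(search_hits(p[0, ], u), "non-empty")
  expect_error(search_hits(p, u$proteins[0, ]), "empty reference")
})

test_that("outfmt6 write -> read -> write is byte-identical", {
  u <- mid_universe()
  p <- sample_type1(u, 31L, per_family = 2L, seed = 4L)
  h <- search_hits(p, u, actual_scoring())
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_outfmt6(h, f1)
  h2 <- read_outfmt6(f1)
  write_outfmt6(h2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(as.data.frame(h2), as.data.frame(h),
               ignore_attr = TRUE)
})

test_that("malformed outfmt6 files raise line-numbered errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  good <- "p1\tS1\t95.00\t31\t1\t0\t1\t31\t5\t35\t1e-08\t55.1"
  writeLines(c(good, "p2\tS2\tonly\tthree"), f)
  expect_error(read_outfmt6(f), "line 2 has 4 column")
  writeLines(c(good,
               "p2\tS2\tNA\t31\t1\t0\t1\t31\t5\t35\t1e-08\t55.1"), f)
  expect_error(read_outfmt6(f), "line 2 has a non-numeric pident")
  writeLines(c(good,
               "p2\tS2\t95.00\t31\t1\t0\t31\t1\t5\t35\t1e-08\t55.1"), f)
  expect_error(read_outfmt6(f), "reversed coordinates")
  # A table above its declared cutoff is rejected.
  writeLines(good, f)
  expect_error(read_outfmt6(f, evalue_max = 1e-10), "cutoff")
})
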