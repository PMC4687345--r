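# Scoring parameters, pairwise local alignment, and Karlin-Altschul
# significance statistics.

#' Alignment scoring parameters
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants used to convert raw Smith-Waterman scores into
#' e-values and bit scores. Defaults follow gapped BLASTP defaults:
#' BLOSUM62 with gap open 11 / extend 1 and the published constants
#' lambda = 0.267, K = 0.041 for that parameter set.
#'
#' @param matrix either the name of a substitution matrix shipped with
#'   Biostrings (e.g. \code{"BLOSUM62"}) or a symmetric named integer
#'   matrix.
#' @param gap_open positive integer, charged once when a gap is opened
#'   (in addition to the per-residue extension cost).
#' @param gap_extend positive integer, per gapped residue.
#' @param lambda,k Karlin-Altschul parameters for the chosen scoring
#'   system.
#' @param effective_db_residues effective search-space size in residues
#'   used for e-values, or \code{NULL} (the default) to use the actual
#'   residue count of the reference at search time. Overriding it lets a
#'   small synthetic reference emulate the e-value behavior of a large
#'   database, where the e <= 10 significance cutoff filters meaningfully.
#' @return An object of class \code{ko_scoring}.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, k = 0.041,
                           effective_db_residues = NULL) {
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stopf("substitution matrix must be square with matching dimnames")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stopf("substitution matrix must be symmetric")
  gap_open <- assert_count(gap_open, "gap_open")
  gap_extend <- assert_count(gap_extend, "gap_extend")
  if (gap_open < gap_extend) stopf("gap_open must be >= gap_extend")
  if (!is.finite(lambda) || lambda <= 0) stopf("lambda must be positive")
  if (!is.finite(k) || k <= 0) stopf("k must be positive")
  if (!is.null(effective_db_residues))
    effective_db_residues <- assert_count(effective_db_residues,
                                          "effective_db_residues")
  structure(list(
    matrix = apply(matrix, c(1, 2), as.integer),
    matrix_name = name,
    alphabet = paste(rownames(matrix), collapse = ""),
    gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, k = k,
    effective_db_residues = effective_db_residues
  ), class = "ko_scoring")
}

#' @export
print.ko_scoring <- function(x, ...) {
  cat(sprintf("Scoring: %s, gap open %d / extend %d, lambda %.3f, K %.3f\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$k))
  cat(sprintf("Effective database residues: %s\n",
              if (is.null(x$effective_db_residues)) "AUTO (actual reference size)"
              else format(x$effective_db_residues)))
  invisible(x)
}

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (ties resolved
#' preferring the diagonal, then the vertical, then the horizontal move).
#'
#' @param query,subject residue strings.
#' @param scoring a \code{\link{scoring_params}} object.
#' @param unknown how to handle residues absent from the matrix alphabet:
#'   \code{"reject"} (default, error naming the offending position) or
#'   \code{"zero"} (score 0 against everything).
#' @return A list with \code{score}, \code{pct_identity},
#'   \code{aln_length}, \code{matches}, \code{mismatches},
#'   \code{gap_opens}, and 1-based inclusive coordinates
#'   \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end}.
#'   If no positive-scoring alignment exists, \code{score} is 0 and
#'   \code{found} is \code{FALSE}.
#' @export
local_align <- function(query, subject, scoring = scoring_params(),
                        unknown = c("reject", "zero")) {
  unknown <- match.arg(unknown)
  if (!nzchar(query) || !nzchar(subject))
    stopf("query and subject must be non-empty")
  r <- cpp_sw_align(query, subject, scoring$matrix, scoring$alphabet,
                    scoring$gap_open, scoring$gap_extend,
                    if (unknown == "reject") 0L else 1L)
  r$pct_identity <- if (r$aln_length > 0) 100 * r$matches / r$aln_length
                    else NA_real_
  r
}

#' Karlin-Altschul e-value of a raw alignment score
#'
#' \code{E = K * m * n * exp(-lambda * S)}: the expected number of chance
#' local alignments scoring at least \code{S} in a search of a query of
#' length \code{m} against \code{n} database residues.
#'
#' @param score raw Smith-Waterman score(s).
#' @param m query length in residues.
#' @param n database size in residues.
#' @param scoring a \code{\link{scoring_params}} object.
#' @return Numeric e-value(s).
#' @export
evalue <- function(score, m, n, scoring = scoring_params()) {
  if (any(m < 1) || any(n < 1)) stopf("m and n must be >= 1")
  scoring$k * m * n * exp(-scoring$lambda * score)
}

#' Bit score of a raw alignment score
#'
#' \code{(lambda * S - ln K) / ln 2}.
#'
#' @inheritParams evalue
#' @return Numeric bit score(s).
#' @export
bitscore <- function(score, scoring = scoring_params()) {
  (scoring$lambda * score - log(scoring$k)) / log(2)
}

# Smallest integer raw score whose e-value is <= evalue_max (at least 1).
min_significant_score <- function(m, n, evalue_max, scoring) {
  s <- ceiling(log(scoring$k * m * n / evalue_max) / scoring$lambda)
  pmax(1L, as.integer(s))
}
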