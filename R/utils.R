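# Internal helpers: seeding, validation, small utilities.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package operations
#' do not disturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage-specific seed from a global seed
#'
#' A simple multiplicative hash salted by the stage name, so one global
#' seed yields reproducible but distinct substreams per pipeline stage.
#'
#' @param seed integer global seed.
#' @param salt character stage name.
#' @return An integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  s <- (as.double(seed) %% 2147483647) * 48271 + h * 7919
  as.integer(s %% 2147483646) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_prob <- function(x, name, open = TRUE) {
  if (length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single number", name)
  if (open && (x <= 0 || x >= 1)) stopf("'%s' must be in (0, 1)", name)
  if (!open && (x < 0 || x > 1)) stopf("'%s' must be in [0, 1]", name)
  as.numeric(x)
}

assert_range <- function(x, name, min = 1L) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || any(x != floor(x)) ||
      x[2] < x[1] || x[1] < min)
    stopf("'%s' must be an integer range c(lo, hi) with lo >= %d", name, min)
  as.integer(x)
}

# Draw one integer uniformly from an integer range per request.
sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

# Deterministic best-hit selection within a hit table: maximum bitscore,
# then minimum evalue, then lexicographically smallest subject id.
best_hit_rows <- function(hits) {
  if (nrow(hits) == 0L) return(integer(0))
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
               method = "radix")
  ord[!duplicated(hits$qseqid[ord])]
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
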