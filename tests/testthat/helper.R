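# Shared fixtures for the test suite. Everything here is small and seeded.

AA20_T <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n) paste(sample(AA20_T, n, TRUE), collapse = "")

# Mutate a protein at the given per-site rate (uniform over other residues).
mutate_protein <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(AA20_T, v[i]), 1)
  paste(v, collapse = "")
}

# A small seeded universe shared by several test files (built once).
tiny_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_universe(universe_config(
        n_families = 12L, members_per_family = c(3L, 8L),
        protein_length = c(120L, 250L), n_hypothetical = 30L,
        min_peptide_support = 81L, seed = 101L))
    cache
  }
})

# A mid-sized universe for behavior/search tests.
mid_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_universe(universe_config(
        n_families = 50L, members_per_family = c(4L, 15L),
        protein_length = c(150L, 400L), n_hypothetical = 150L,
        seed = 202L))
    cache
  }
})

# Scoring with the actual (small) reference as the e-value space, for
# tests that should not depend on the calibrated default.
actual_scoring <- function() scoring_params()

# Independent exhaustive-DP oracle (Biostrings) with identical scoring.
oracle_score <- function(q, s) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  max(0, Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)))
}

# A hand-checkable hit table.
manual_hits <- function(df, evalue_max = 10) {
  need <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- switch(col, pident = 90, length = 31L, mismatch = 3L,
                        gapopen = 0L, qstart = 1L, qend = 31L,
                        sstart = 1L, send = 31L, evalue = 1e-5,
                        bitscore = 50)
  }
  structure(df[, need], class = c("ko_hits", "data.frame"),
            evalue_max = evalue_max, self_hits_excluded = FALSE,
            reference_size = c(proteins = NA, residues = NA))
}
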