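# Peptide test sets: fixed-length non-identical fragments from family
# members (Type 1), screened hypothetical proteins (Type 2) and the large
# abundance-validation set (Type 3).

new_peptide_set <- function(df, label, seed, params, skipped = character(0),
                            truncated = character(0)) {
  rownames(df) <- NULL
  structure(df, class = c("ko_peptides", "data.frame"),
            label = label, seed = seed, params = params,
            skipped = skipped, truncated = truncated)
}

#' @export
print.ko_peptides <- function(x, ...) {
  cat(sprintf("Peptide set %s: %d peptides from %d proteins\n",
              attr(x, "label"), nrow(x),
              length(unique(x$source_protein_id))))
  if (length(attr(x, "skipped")))
    cat(sprintf("  skipped (too short): %d source(s)\n",
                length(attr(x, "skipped"))))
  print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# Draw up to `per` distinct fixed-length substrings of one protein by
# rejection sampling over start positions (cap: 100 * per attempts).
# Returns 0-based starts of the kept peptides.
draw_distinct_substrings <- function(sequence, len, per) {
  L <- nchar(sequence)
  n_starts <- L - len + 1L
  starts <- integer(0)
  seen <- character(0)
  attempts <- 0L
  while (length(starts) < per && attempts < 100L * per) {
    attempts <- attempts + 1L
    s <- sample.int(n_starts, 1L) - 1L
    pep <- substr(sequence, s + 1L, s + len)
    if (!(pep %in% seen)) {
      seen <- c(seen, pep)
      starts <- c(starts, s)
    }
  }
  starts
}

sample_peptides_from <- function(proteins, family_ids, len, per, label,
                                 seed, skip_if_infeasible) {
  with_seed(seed, {
    rows <- vector("list", nrow(proteins))
    skipped <- character(0)
    truncated <- character(0)
    for (i in seq_len(nrow(proteins))) {
      pid <- proteins$protein_id[i]
      sq <- proteins$sequence[i]
      L <- nchar(sq)
      per_i <- if (length(per) > 1) sample.int(per[2] - per[1] + 1L, 1L) +
                 per[1] - 1L else per
      if (L < len || (skip_if_infeasible && (L - len + 1L) < per_i)) {
        skipped <- c(skipped, pid)
        next
      }
      starts <- draw_distinct_substrings(sq, len, per_i)
      if (length(starts) < per_i) truncated <- c(truncated, pid)
      if (!length(starts)) next
      rows[[i]] <- data.frame(
        peptide_id = sprintf("%s|%d-%d", pid, starts + 1L, starts + len),
        source_protein_id = pid,
        source_family_id = family_ids[i],
        start = starts, length = len,
        sequence = substring(sq, starts + 1L, starts + len),
        stringsAsFactors = FALSE)
    }
    if (length(skipped))
      warnf("%s: %d source protein(s) skipped (shorter than needed for %d distinct %d-mers)",
            label, length(skipped), if (length(per) > 1) per[1] else per, len)
    if (length(truncated))
      warnf("%s: %d protein(s) yielded fewer peptides than requested",
            label, length(truncated))
    df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(df))
      df <- data.frame(peptide_id = character(0),
                       source_protein_id = character(0),
                       source_family_id = character(0),
                       start = integer(0), length = integer(0),
                       sequence = character(0), stringsAsFactors = FALSE)
    new_peptide_set(df, label, seed,
                    list(length = len, per = per),
                    skipped = skipped, truncated = truncated)
  })
}

#' Type 1 peptides: fixed-length fragments from one member per family
#'
#' For each family, one member is chosen uniformly at random and
#' \code{per_family} distinct substrings of the requested length are drawn
#' from it at uniform random start positions. Families whose chosen member
#' cannot yield the requested number of distinct peptides are skipped with
#' a warning (the mechanism behind declining totals at longer peptide
#' lengths when short proteins are present).
#'
#' @param universe a \code{ko_universe}.
#' @param length peptide length in residues (the standard panel spans 11
#'   to 81).
#' @param per_family peptides per family (default 3).
#' @param seed integer seed.
#' @return A \code{ko_peptides} data frame (\code{peptide_id},
#'   \code{source_protein_id}, \code{source_family_id}, 0-based
#'   \code{start}, \code{length}, \code{sequence}); skipped families are
#'   recorded in \code{attr(, "skipped")}.
#' @export
sample_type1 <- function(universe, length, per_family = 3L, seed = 1L) {
  stopifnot(inherits(universe, "ko_universe"))
  length <- assert_count(length, "length")
  per_family <- assert_count(per_family, "per_family")
  if (length < 11L || length > 81L)
    warnf("peptide length %d is outside the standard 11-81 panel", length)
  fam <- family_proteins(universe)
  if (!nrow(fam)) stopf("universe has no family proteins")
  with_seed(derive_seed(seed, "type1-pick"), {
    pick <- vapply(split(seq_len(nrow(fam)), fam$family_id),
                   function(idx) if (base::length(idx) == 1L) idx
                                 else sample(idx, 1L), 1L)
  })
  chosen <- fam[pick, , drop = FALSE]
  sample_peptides_from(chosen, chosen$family_id, length, per_family,
                       sprintf("Type1_%d", length), seed,
                       skip_if_infeasible = TRUE)
}

#' Type 2 peptides: fragments of screened hypothetical proteins
#'
#' @param retained data frame with \code{protein_id} and \code{sequence}
#'   columns, typically the \code{retained} element of
#'   \code{\link{screen_homology}}.
#' @param length peptide length (default 31).
#' @param per_protein peptides per protein (default 3).
#' @param seed integer seed.
#' @return A \code{ko_peptides} data frame; \code{source_family_id} is
#'   \code{NA} throughout.
#' @export
sample_type2 <- function(retained, length = 31L, per_protein = 3L, seed = 1L) {
  length <- assert_count(length, "length")
  per_protein <- assert_count(per_protein, "per_protein")
  if (!nrow(retained)) {
    warnf("no retained proteins; returning an empty Type 2 set")
    return(sample_peptides_from(retained[0, , drop = FALSE], character(0),
                                length, per_protein, "Type2", seed, TRUE))
  }
  sample_peptides_from(retained, rep(NA_character_, nrow(retained)),
                       length, per_protein, "Type2", seed,
                       skip_if_infeasible = FALSE)
}

#' Type 3 peptides: the abundance-validation simulation set
#'
#' Selects \code{ceiling(member_fraction * size)} members of each family
#' (at least one) and draws a uniform 20-40 (by default) distinct
#' fixed-length substrings from each selected protein.
#'
#' @param universe a \code{ko_universe}.
#' @param member_fraction fraction of members selected per family, in
#'   (0, 1].
#' @param peptides_per_protein integer range of peptides per selected
#'   protein.
#' @param length peptide length (default 31).
#' @param seed integer seed.
#' @return A \code{ko_peptides} data frame.
#' @export
sample_type3 <- function(universe, member_fraction = 0.10,
                         peptides_per_protein = c(20L, 40L),
                         length = 31L, seed = 1L) {
  stopifnot(inherits(universe, "ko_universe"))
  if (member_fraction <= 0 || member_fraction > 1)
    stopf("member_fraction must be in (0, 1]")
  peptides_per_protein <- assert_range(peptides_per_protein,
                                       "peptides_per_protein")
  length <- assert_count(length, "length")
  fam <- family_proteins(universe)
  if (!nrow(fam)) stopf("universe has no family proteins")
  with_seed(derive_seed(seed, "type3-pick"), {
    sel <- unlist(lapply(split(seq_len(nrow(fam)), fam$family_id),
                         function(idx) {
                           n <- max(1L, ceiling(member_fraction *
                                                  base::length(idx)))
                           if (base::length(idx) == 1L) idx
                           else sample(idx, n)
                         }), use.names = FALSE)
  })
  chosen <- fam[sort(sel), , drop = FALSE]
  sample_peptides_from(chosen, chosen$family_id, length,
                       peptides_per_protein, "Type3", seed,
                       skip_if_infeasible = FALSE)
}

#' Write / read a peptide set
#'
#' FASTA of the peptide sequences plus a truth TSV
#' (\code{peptide_id}, \code{source_protein_id}, \code{source_family_id},
#' \code{start}, \code{length}).
#'
#' @param peptides a \code{ko_peptides} data frame.
#' @param fasta,truth output file paths.
#' @return Invisibly \code{NULL}.
#' @export
write_peptides <- function(peptides, fasta, truth) {
  seqs <- Biostrings::AAStringSet(setNames(peptides$sequence,
                                           peptides$peptide_id))
  Biostrings::writeXStringSet(seqs, filepath = fasta, width = 80L)
  tr <- peptides[, c("peptide_id", "source_protein_id", "source_family_id",
                     "start", "length")]
  tr$source_family_id[is.na(tr$source_family_id)] <- "-"
  write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(NULL)
}

#' @rdname write_peptides
#' @param label label for the reconstructed set.
#' @export
read_peptides <- function(fasta, truth, label = "imported") {
  seqs <- Biostrings::readAAStringSet(fasta)
  tr <- read.table(truth, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "integer", "integer"))
  if (!identical(tr$peptide_id, names(seqs)))
    stopf("truth TSV does not match peptide FASTA (ids or order differ)")
  tr$source_family_id[tr$source_family_id == "-"] <- NA_character_
  tr$sequence <- as.character(seqs)
  new_peptide_set(tr, label, NA_integer_, list())
}
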