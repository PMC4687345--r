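# Redundancy reduction and homology screening of the hypothetical-protein
# ("unknown") space, used to define the Type 2 peptide sources.

#' Greedy single-pass identity clustering
#'
#' A CD-HIT-style greedy clustering: proteins are processed by decreasing
#' length; each joins the earliest-founded cluster whose representative it
#' matches at \code{>= identity_threshold} (identity = matches over the
#' shorter sequence length, from the best local alignment), otherwise it
#' founds a new cluster. A shared 3-mer count prescreen limits the
#' alignments attempted; assignments are never revised.
#'
#' @param proteins data frame with \code{protein_id} and \code{sequence}.
#' @param identity_threshold fraction in (0, 1] (default 0.70).
#' @param scoring a \code{\link{scoring_params}} object (alignment only;
#'   the Karlin-Altschul constants are not used here).
#' @return A \code{ko_clusters} data frame (\code{protein_id},
#'   \code{representative_id}) with the threshold in
#'   \code{attr(, "identity_threshold")}. Cluster representatives map to
#'   themselves.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.70,
                           scoring = scoring_params()) {
  if (!nrow(proteins)) stopf("at least one protein is required")
  if (identity_threshold <= 0 || identity_threshold > 1)
    stopf("identity_threshold must be in (0, 1]")
  ord <- order(-nchar(proteins$sequence))
  rep_idx <- cpp_greedy_cluster(proteins$sequence[ord], identity_threshold,
                                scoring$matrix, scoring$alphabet,
                                scoring$gap_open, scoring$gap_extend)
  out <- data.frame(protein_id = proteins$protein_id[ord],
                    representative_id = proteins$protein_id[ord][rep_idx],
                    stringsAsFactors = FALSE)
  out <- out[match(proteins$protein_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ko_clusters", "data.frame"),
            identity_threshold = identity_threshold)
}

#' @export
print.ko_clusters <- function(x, ...) {
  cat(sprintf("Greedy clustering at %.0f%% identity: %d sequences, %d clusters\n",
              100 * attr(x, "identity_threshold"), nrow(x),
              length(unique(x$representative_id))))
  print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Cluster representatives as a protein data frame
#'
#' @param clusters a \code{ko_clusters} object.
#' @param proteins the data frame that was clustered.
#' @return The subset of \code{proteins} that are representatives.
#' @export
cluster_representatives <- function(clusters, proteins) {
  keep <- proteins$protein_id %in% unique(clusters$representative_id)
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen representatives for homology to the family reference
#'
#' A representative is removed when some family protein aligns to it with
#' query coverage \code{>= coverage_min} (aligned query span over full
#' query length) and alignment identity \code{>= identity_min}. The three
#' standard identity thresholds (0.70, 0.50, 0.35) define progressively
#' stricter notions of the "unknown protein space". A shared-word count
#' prescreen selects candidate reference proteins; its sensitivity for
#' remote (~35% identity) homologs is partial, which matters only when
#' such homologs exist in the reference.
#'
#' @param representatives data frame with \code{protein_id},
#'   \code{sequence}.
#' @param universe a \code{ko_universe} providing the family reference.
#' @param coverage_min minimum query coverage (default 0.70).
#' @param identity_min minimum alignment identity (default 0.70).
#' @param scoring a \code{\link{scoring_params}} object.
#' @return A list with \code{retained} and \code{removed} (data frames of
#'   the input rows) and \code{report} (per removed representative: the
#'   reference protein, coverage and identity that triggered removal).
#' @export
screen_homology <- function(representatives, universe,
                            coverage_min = 0.70, identity_min = 0.70,
                            scoring = scoring_params()) {
  if (!nrow(representatives)) stopf("representatives must be non-empty")
  assert_prob(coverage_min, "coverage_min")
  if (identity_min <= 0 || identity_min > 1)
    stopf("identity_min must be in (0, 1]")
  refs <- family_proteins(universe)
  cand <- cpp_kmer_candidates(representatives$sequence, refs$sequence,
                              scoring$alphabet)
  removed <- logical(nrow(representatives))
  hit_ref <- character(nrow(representatives))
  hit_cov <- hit_id <- numeric(nrow(representatives))
  for (i in seq_len(nrow(representatives))) {
    qlen <- nchar(representatives$sequence[i])
    for (s in cand[[i]]) {
      a <- cpp_sw_align(representatives$sequence[i], refs$sequence[s],
                        scoring$matrix, scoring$alphabet,
                        scoring$gap_open, scoring$gap_extend, 0L)
      if (!a$found) next
      cov <- (a$q_end - a$q_start + 1) / qlen
      ident <- a$matches / a$aln_length
      if (cov >= coverage_min && ident >= identity_min) {
        removed[i] <- TRUE
        hit_ref[i] <- refs$protein_id[s]
        hit_cov[i] <- cov
        hit_id[i] <- ident
        break
      }
    }
  }
  report <- data.frame(protein_id = representatives$protein_id[removed],
                       matched_reference = hit_ref[removed],
                       coverage = hit_cov[removed],
                       identity = hit_id[removed],
                       stringsAsFactors = FALSE)
  ret <- representatives[!removed, , drop = FALSE]
  rem <- representatives[removed, , drop = FALSE]
  rownames(ret) <- rownames(rem) <- NULL
  message(sprintf("homology screen (cov >= %.2f, id >= %.2f): removed %d of %d, %d retained",
                  coverage_min, identity_min, nrow(rem),
                  nrow(representatives), nrow(ret)))
  list(retained = ret, removed = rem, report = report,
       coverage_min = coverage_min, identity_min = identity_min)
}
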