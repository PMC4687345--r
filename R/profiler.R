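# Alignment-behavior analyses: parental vs non-parental classification,
# per-length summary tables, family-size identity trends, EC-hierarchy
# similarity, ROC threshold grids, and the resampled length-effect ANOVA.

#' Classify hits as parental or non-parental
#'
#' A hit is parental when the subject protein belongs to the same family
#' the query peptide was extracted from. Hits to unlabeled (hypothetical)
#' subjects count as non-parental. Self-hits (subject = source protein)
#' are flagged.
#'
#' @param hits a \code{ko_hits} data frame.
#' @param peptides the \code{ko_peptides} truth for the queried set.
#' @param universe a \code{ko_universe} (or a data frame mapping
#'   \code{protein_id} to \code{family_id}).
#' @return A \code{ko_classified} data frame: the hit columns plus
#'   \code{peptide_length}, \code{source_family_id},
#'   \code{subject_family_id}, \code{parental}, \code{is_self} and
#'   \code{coverage} (alignment length over peptide length, percent).
#' @export
classify_hits <- function(hits, peptides, universe) {
  prot <- if (inherits(universe, "ko_universe")) universe$proteins
          else universe
  qi <- match(hits$qseqid, peptides$peptide_id)
  if (anyNA(qi))
    stopf("hit table contains query ids absent from the peptide truth (e.g. '%s')",
          hits$qseqid[which(is.na(qi))[1]])
  si <- match(hits$sseqid, prot$protein_id)
  if (anyNA(si))
    stopf("hit table contains subject ids absent from the universe (e.g. '%s')",
          hits$sseqid[which(is.na(si))[1]])
  out <- as.data.frame(hits)
  out$peptide_length <- peptides$length[qi]
  out$source_family_id <- peptides$source_family_id[qi]
  out$subject_family_id <- prot$family_id[si]
  out$parental <- !is.na(out$source_family_id) &
    !is.na(out$subject_family_id) &
    out$source_family_id == out$subject_family_id
  out$is_self <- out$sseqid == peptides$source_protein_id[qi]
  out$coverage <- 100 * out$length / out$peptide_length
  structure(out, class = c("ko_classified", "data.frame"),
            evalue_max = attr(hits, "evalue_max"))
}

#' Per-length alignment behavior summary
#'
#' One row per peptide length: total peptides, fraction with at least one
#' significant hit, total hits, parental/non-parental hit counts and
#' percentages, and the same split for best hits (best = maximum bit
#' score; ties broken by minimum e-value, then subject id). Self-hits are
#' excluded by default, as in the behavior analyses.
#'
#' @param classified a \code{ko_classified} data frame (one or more
#'   peptide lengths).
#' @param peptides the \code{ko_peptides} truth (defines the peptide
#'   denominators, including peptides with zero hits).
#' @param include_self keep self-hits in the statistics (default
#'   \code{FALSE}).
#' @return A data frame with the 8-column behavior summary per length.
#' @export
behavior_table <- function(classified, peptides, include_self = FALSE) {
  cl <- classified
  if (!include_self) cl <- cl[!cl$is_self, , drop = FALSE]
  lens <- sort(unique(peptides$length))
  rows <- lapply(lens, function(L) {
    peps <- peptides[peptides$length == L, , drop = FALSE]
    h <- cl[cl$peptide_length == L, , drop = FALSE]
    aligned <- length(unique(h$qseqid))
    bh <- h[best_hit_rows(h), , drop = FALSE]
    data.frame(
      peptide_length = L,
      total_peptides = nrow(peps),
      aligned = aligned,
      fraction_aligned = round(pct(aligned, nrow(peps)), 1),
      total_hits = nrow(h),
      hits_parental = sum(h$parental),
      hits_parental_pct = round(pct(sum(h$parental), nrow(h)), 1),
      hits_nonparental = sum(!h$parental),
      hits_nonparental_pct = round(pct(sum(!h$parental), nrow(h)), 1),
      besthits_parental = sum(bh$parental),
      besthits_parental_pct = round(pct(sum(bh$parental), nrow(bh)), 1),
      besthits_nonparental = sum(!bh$parental),
      besthits_nonparental_pct = round(pct(sum(!bh$parental), nrow(bh)), 1))
  })
  do.call(rbind, rows)
}

#' Family size versus parental-hit identity
#'
#' Per family, the median alignment identity over all parental hits, with
#' the family's member count; plus the Spearman rank correlation between
#' size and median identity. In databases with uneven family
#' representation, larger families cover more evolutionary space and
#' deflate the median identity of true-positive hits.
#'
#' @param classified a \code{ko_classified} data frame.
#' @param catalog a family catalog (\code{family_id}, \code{n_members}),
#'   e.g. \code{universe$family_catalog}.
#' @param include_self keep self-hits (default \code{FALSE}).
#' @return A list: \code{table} (family_id, family_size,
#'   median_identity, n_hits), \code{spearman_rho}, and
#'   \code{n_families_without_parental_hits}.
#' @export
ko_size_identity_trend <- function(classified, catalog,
                                   include_self = FALSE) {
  cl <- classified[classified$parental, , drop = FALSE]
  if (!include_self) cl <- cl[!cl$is_self, , drop = FALSE]
  if (!nrow(cl)) {
    return(list(table = data.frame(family_id = character(0),
                                   family_size = integer(0),
                                   median_identity = numeric(0),
                                   n_hits = integer(0)),
                spearman_rho = NA_real_,
                n_families_without_parental_hits = nrow(catalog)))
  }
  sp <- split(cl$pident, cl$subject_family_id)
  tab <- data.frame(family_id = names(sp),
                    family_size = catalog$n_members[
                      match(names(sp), catalog$family_id)],
                    median_identity = vapply(sp, median, 0),
                    n_hits = lengths(sp),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  rho <- if (nrow(tab) > 2)
    suppressWarnings(cor(tab$family_size, tab$median_identity,
                         method = "spearman")) else NA_real_
  list(table = tab, spearman_rho = rho,
       n_families_without_parental_hits =
         sum(!(catalog$family_id %in% tab$family_id)))
}

ec_split <- function(ec) strsplit(ec, ".", fixed = TRUE)

# Depth of agreement of two 4-level EC labels (0-4).
ec_match_depth <- function(a, b) {
  pa <- ec_split(a); pb <- ec_split(b)
  mapply(function(x, y) {
    k <- 0L
    for (i in seq_len(min(length(x), length(y), 4L))) {
      if (x[i] == y[i]) k <- i else break
    }
    k
  }, pa, pb)
}

#' EC-hierarchy similarity of non-parental alignments
#'
#' Over non-parental, non-self hits where both the query's source family
#' and the subject's family carry EC labels, the fraction of comparisons
#' agreeing at EC level 1, levels 1-2, levels 1-3 and all four levels.
#' Agreement decreasing only slowly with depth is the signature of
#' domain sharing between functionally related families.
#'
#' @param classified a \code{ko_classified} data frame.
#' @param universe a \code{ko_universe} (source of the EC labels).
#' @return A list of class \code{ko_ec_similarity}: \code{fractions}
#'   (named numeric, levels 1-4), \code{n_comparisons}. When no eligible
#'   comparison exists the fractions are \code{NA} (an explicitly empty
#'   result, not zeros).
#' @export
ec_similarity <- function(classified, universe) {
  cat_ec <- universe$family_catalog
  cl <- classified[!classified$parental & !classified$is_self, , drop = FALSE]
  q_ec <- cat_ec$ec[match(cl$source_family_id, cat_ec$family_id)]
  s_ec <- cat_ec$ec[match(cl$subject_family_id, cat_ec$family_id)]
  ok <- !is.na(q_ec) & !is.na(s_ec)
  n <- sum(ok)
  if (n == 0) {
    out <- list(fractions = setNames(rep(NA_real_, 4),
                                     paste0("level", 1:4)),
                n_comparisons = 0L)
    return(structure(out, class = "ko_ec_similarity"))
  }
  depth <- ec_match_depth(q_ec[ok], s_ec[ok])
  fractions <- vapply(1:4, function(k) mean(depth >= k), 0)
  names(fractions) <- paste0("level", 1:4)
  structure(list(fractions = fractions, n_comparisons = n),
            class = "ko_ec_similarity")
}

#' @export
print.ko_ec_similarity <- function(x, ...) {
  if (x$n_comparisons == 0) {
    cat("EC similarity: no eligible non-parental comparisons\n")
  } else {
    cat(sprintf("EC similarity over %d non-parental comparisons:\n",
                x$n_comparisons))
    cat(sprintf("  level 1: %.1f%%; levels 1-2: %.1f%%; levels 1-3: %.1f%%; all 4: %.1f%%\n",
                100 * x$fractions[1], 100 * x$fractions[2],
                100 * x$fractions[3], 100 * x$fractions[4]))
  }
  invisible(x)
}

#' ROC grid over coverage and identity thresholds
#'
#' For a random sample of alignments, each (coverage, identity) threshold
#' pair predicts "parental" when query coverage and alignment identity
#' both reach the thresholds; the true label is parental origin. True-
#' and false-positive rates are computed over the same sample for every
#' grid cell.
#'
#' @param classified a \code{ko_classified} data frame containing both
#'   parental and non-parental alignments.
#' @param n_alignments sample size (default 10000; capped at the number
#'   of available alignments).
#' @param coverage_grid,identity_grid percent thresholds (defaults
#'   50-80 by 10 and 40-90 by 10).
#' @param seed integer seed for the sample.
#' @param include_self keep self-hits (default \code{FALSE}).
#' @return A data frame with one row per grid cell: \code{coverage_min},
#'   \code{identity_min}, \code{tpr}, \code{fpr}, \code{n_alignments}.
#' @export
roc_grid <- function(classified, n_alignments = 10000L,
                     coverage_grid = seq(50, 80, 10),
                     identity_grid = seq(40, 90, 10), seed = 1L,
                     include_self = FALSE) {
  cl <- classified
  if (!include_self) cl <- cl[!cl$is_self, , drop = FALSE]
  if (!any(cl$parental)) stopf("sample contains no parental alignments")
  if (!any(!cl$parental)) stopf("sample contains no non-parental alignments")
  n <- min(n_alignments, nrow(cl))
  cl <- with_seed(derive_seed(seed, "roc-sample"),
                  cl[sample.int(nrow(cl), n), , drop = FALSE])
  grid <- expand.grid(coverage_min = coverage_grid,
                      identity_min = identity_grid)
  pos <- cl$parental
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pred <- cl$coverage >= grid$coverage_min[i] &
      cl$pident >= grid$identity_min[i]
    data.frame(coverage_min = grid$coverage_min[i],
               identity_min = grid$identity_min[i],
               tpr = sum(pred & pos) / sum(pos),
               fpr = sum(pred & !pos) / sum(!pos),
               n_alignments = n)
  })
  do.call(rbind, res)
}

#' Length-effect ANOVA on parental/non-parental identity differences
#'
#' Repeatedly draws, for each peptide length, \code{n_per_length}
#' parental and \code{n_per_length} non-parental alignment identities,
#' pairs them at random, and fits a one-way ANOVA of the per-pair
#' identity difference on peptide length. A large mean p-value over the
#' iterations indicates that the parental/non-parental identity contrast
#' is independent of peptide length.
#'
#' @param classified either a \code{ko_classified} data frame or any data
#'   frame with \code{peptide_length}, \code{pident} and \code{parental}
#'   columns.
#' @param lengths peptide lengths to use (default: all present; the
#'   standard analysis uses 21-81, excluding 11).
#' @param n_per_length hits sampled per class per length (default 500).
#' @param iterations resampling iterations (default 100).
#' @param seed integer seed.
#' @param include_self keep self-hits if the column is present (default
#'   \code{FALSE}).
#' @return A list of class \code{ko_anova}: \code{p_values},
#'   \code{mean_p}, \code{lengths}, \code{n_per_length}.
#' @export
length_effect_anova <- function(classified, lengths = NULL,
                                n_per_length = 500L, iterations = 100L,
                                seed = 1L, include_self = FALSE) {
  cl <- classified
  if (!include_self && "is_self" %in% names(cl))
    cl <- cl[!cl$is_self, , drop = FALSE]
  if (is.null(lengths)) lengths <- sort(unique(cl$peptide_length))
  par_ident <- lapply(lengths, function(L)
    cl$pident[cl$peptide_length == L & cl$parental])
  non_ident <- lapply(lengths, function(L)
    cl$pident[cl$peptide_length == L & !cl$parental])
  for (i in seq_along(lengths)) {
    if (length(par_ident[[i]]) < n_per_length ||
        length(non_ident[[i]]) < n_per_length)
      stopf("length %d has fewer than %d parental or non-parental hits",
            lengths[i], n_per_length)
  }
  p_values <- with_seed(derive_seed(seed, "anova"), {
    vapply(seq_len(iterations), function(it) {
      diffs <- unlist(lapply(seq_along(lengths), function(i) {
        a <- sample(par_ident[[i]], n_per_length)
        b <- sample(non_ident[[i]], n_per_length)
        a - b
      }))
      grp <- factor(rep(lengths, each = n_per_length))
      fit <- aov(diffs ~ grp)
      summary(fit)[[1]][["Pr(>F)"]][1]
    }, 0)
  })
  structure(list(p_values = p_values, mean_p = mean(p_values),
                 lengths = lengths, n_per_length = n_per_length),
            class = "ko_anova")
}

#' @export
print.ko_anova <- function(x, ...) {
  cat(sprintf(paste0("Length-effect ANOVA: mean p = %.4f over %d iterations",
                     " (%d hits/class/length, lengths %s)\n"),
              x$mean_p, length(x$p_values), x$n_per_length,
              paste(x$lengths, collapse = ",")))
  invisible(x)
}
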