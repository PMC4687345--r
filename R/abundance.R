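# Frequency-weighted family abundance estimation, the sparse/low-identity
# filter, deviation statistics, and the composite subset experiment.

NONFAMILY <- "NONFAMILY"

resolve_catalog <- function(x) {
  if (inherits(x, "ko_universe"))
    return(list(proteins = x$proteins, families = x$family_catalog))
  if (is.list(x) && !is.null(x$proteins) && !is.null(x$family_catalog))
    return(list(proteins = x$proteins, families = x$family_catalog))
  stopf("expected a ko_universe (or a list with $proteins and $family_catalog)")
}

#' Per-peptide frequency weights
#'
#' For every peptide with at least one significant hit: its hit count
#' \code{N}, its frequency weight \code{1/N}, and the alignment identity
#' of its best hit (maximum bit score; ties broken by minimum e-value,
#' then subject id).
#'
#' @param hits a \code{ko_hits} data frame.
#' @return A \code{ko_weights} data frame (\code{peptide_id},
#'   \code{n_hits}, \code{weight}, \code{best_hit_identity}). Peptides
#'   with zero hits are simply absent.
#' @export
peptide_weights <- function(hits) {
  bh <- hits[best_hit_rows(hits), , drop = FALSE]
  n <- as.integer(table(hits$qseqid)[bh$qseqid])
  out <- data.frame(peptide_id = bh$qseqid,
                    n_hits = n,
                    weight = 1 / n,
                    best_hit_identity = bh$pident,
                    stringsAsFactors = FALSE)
  out <- out[order(out$peptide_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ko_weights", "data.frame"))
}

#' Remove sparse, low-identity peptides before abundance estimation
#'
#' In \code{ALL} mode (the default) a peptide is removed when its hit
#' count is below \code{min_hits} AND its best-hit identity is below
#' \code{min_best_identity}; in \code{ANY} mode, when either criterion
#' holds. This is the filter that suppresses the spurious mass
#' contributed by peptides from proteins unrelated to the reference
#' families.
#'
#' @param hits a \code{ko_hits} data frame.
#' @param weights the \code{\link{peptide_weights}} of \code{hits}.
#' @param min_hits hit-count threshold (default 50).
#' @param min_best_identity best-hit identity threshold in percent
#'   (default 55).
#' @param combine \code{"ALL"} or \code{"ANY"}.
#' @return A list: \code{hits} and \code{weights} restricted to retained
#'   peptides, and \code{report} (per removed peptide: which criteria
#'   fired).
#' @export
apply_filter <- function(hits, weights, min_hits = 50L,
                         min_best_identity = 55,
                         combine = c("ALL", "ANY")) {
  combine <- match.arg(combine)
  min_hits <- assert_count(min_hits, "min_hits")
  if (min_best_identity < 0 || min_best_identity > 100)
    stopf("min_best_identity must be in [0, 100]")
  low_hits <- weights$n_hits < min_hits
  low_ident <- weights$best_hit_identity < min_best_identity
  drop <- if (combine == "ALL") low_hits & low_ident else low_hits | low_ident
  report <- data.frame(peptide_id = weights$peptide_id[drop],
                       n_hits = weights$n_hits[drop],
                       best_hit_identity = weights$best_hit_identity[drop],
                       low_hit_count = low_hits[drop],
                       low_best_identity = low_ident[drop],
                       stringsAsFactors = FALSE)
  keep_ids <- weights$peptide_id[!drop]
  kept_hits <- hits[hits$qseqid %in% keep_ids, , drop = FALSE]
  rownames(kept_hits) <- NULL
  kept_w <- weights[!drop, , drop = FALSE]
  rownames(kept_w) <- NULL
  list(hits = kept_hits, weights = kept_w, report = report,
       spec = list(min_hits = min_hits,
                   min_best_identity = min_best_identity,
                   combine = combine))
}

new_abundance <- function(df, nonfamily, allocation, n_used, settings) {
  rownames(df) <- NULL
  structure(df, class = c("ko_abundance", "data.frame"),
            nonfamily = nonfamily, allocation = allocation,
            n_peptides_used = n_used, settings = settings)
}

#' @export
print.ko_abundance <- function(x, ...) {
  cat(sprintf("Abundance profile (%s): %d families, %d peptides, NONFAMILY = %.3f\n",
              attr(x, "allocation"), nrow(x), attr(x, "n_peptides_used"),
              attr(x, "nonfamily")))
  print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Frequency-weighted family abundance
#'
#' Family abundance is the sum of the frequency weights of the peptides
#' aligned to its member proteins. Under \code{PER_HIT} allocation (the
#' default) each of a peptide's \code{N} hits carries mass \code{1/N},
#' so every weighted peptide contributes total mass 1 and the profile
#' sums (with the \code{NONFAMILY} bucket) to the number of weighted
#' peptides. Under \code{PER_FAMILY}, a family gains \code{1/N} once if
#' the peptide hits any of its members. Hits to unlabeled (hypothetical)
#' subjects accumulate in the \code{NONFAMILY} bucket.
#'
#' @param hits a \code{ko_hits} data frame.
#' @param weights the \code{\link{peptide_weights}} of \code{hits}.
#' @param universe a \code{ko_universe} (subject-to-family mapping and
#'   family catalog).
#' @param allocation \code{"PER_HIT"} or \code{"PER_FAMILY"}.
#' @return A \code{ko_abundance} data frame (\code{family_id},
#'   \code{weighted_count}, \code{n_peptides}) over every catalog family
#'   (zeros where nothing aligned), with the \code{NONFAMILY} mass, the
#'   allocation mode and peptide counts as attributes.
#' @export
weighted_abundance <- function(hits, weights, universe,
                               allocation = c("PER_HIT", "PER_FAMILY")) {
  allocation <- match.arg(allocation)
  cat_ <- resolve_catalog(universe)
  si <- match(hits$sseqid, cat_$proteins$protein_id)
  if (anyNA(si))
    stopf("subject '%s' is absent from the catalog",
          hits$sseqid[which(is.na(si))[1]])
  fam <- cat_$proteins$family_id[si]
  fam[is.na(fam)] <- NONFAMILY
  w <- weights$weight[match(hits$qseqid, weights$peptide_id)]
  if (anyNA(w))
    stopf("hit table contains peptides absent from the weight table")
  if (allocation == "PER_FAMILY") {
    key <- !duplicated(paste(hits$qseqid, fam, sep = "\r"))
    fam <- fam[key]; w <- w[key]; qs <- hits$qseqid[key]
  } else qs <- hits$qseqid
  mass <- vapply(split(w, fam), sum, 0)
  npep <- vapply(split(qs, fam), function(q) length(unique(q)), 0L)
  fams <- cat_$families$family_id
  df <- data.frame(family_id = fams,
                   weighted_count = unname(mass[fams]),
                   n_peptides = unname(npep[fams]),
                   stringsAsFactors = FALSE)
  df$weighted_count[is.na(df$weighted_count)] <- 0
  df$n_peptides[is.na(df$n_peptides)] <- 0L
  new_abundance(df,
                nonfamily = if (NONFAMILY %in% names(mass))
                  mass[[NONFAMILY]] else 0,
                allocation = allocation,
                n_used = nrow(weights),
                settings = list(evalue_max = attr(hits, "evalue_max")))
}

#' True per-family peptide counts
#'
#' The unweighted count of peptides whose source family is each catalog
#' family; unlabeled peptides are counted in the \code{NONFAMILY} bucket
#' with a warning.
#'
#' @param peptides a \code{ko_peptides} data frame.
#' @param universe a \code{ko_universe} (family catalog).
#' @return A \code{ko_abundance} data frame over every catalog family.
#' @export
true_abundance <- function(peptides, universe) {
  cat_ <- resolve_catalog(universe)
  fam <- peptides$source_family_id
  n_unlab <- sum(is.na(fam))
  if (n_unlab)
    warnf("%d unlabeled peptide(s) counted in the NONFAMILY bucket", n_unlab)
  fam[is.na(fam)] <- NONFAMILY
  counts <- table(fam)
  fams <- cat_$families$family_id
  df <- data.frame(family_id = fams,
                   weighted_count = as.numeric(counts[fams]),
                   n_peptides = as.integer(counts[fams]),
                   stringsAsFactors = FALSE)
  df$weighted_count[is.na(df$weighted_count)] <- 0
  df$n_peptides[is.na(df$n_peptides)] <- 0L
  new_abundance(df,
                nonfamily = if (NONFAMILY %in% names(counts))
                  as.numeric(counts[[NONFAMILY]]) else 0,
                allocation = "TRUE_COUNT",
                n_used = nrow(peptides), settings = list())
}

#' Deviation of an estimated profile from the truth
#'
#' Mean and standard deviation of the absolute per-family difference
#' between the estimated and true profiles, over the union of their
#' family catalogs (missing families imputed as zero), plus the Pearson
#' correlation of the two vectors.
#'
#' @param estimated,truth \code{ko_abundance} profiles.
#' @return A list of class \code{ko_deviation}: \code{mean_abs_dev},
#'   \code{sd_abs_dev}, \code{pearson_r}, \code{n_families} and the
#'   per-family \code{table}.
#' @export
deviation_stats <- function(estimated, truth) {
  fams <- union(estimated$family_id, truth$family_id)
  if (!length(fams)) stopf("both profiles are empty")
  e <- estimated$weighted_count[match(fams, estimated$family_id)]
  t_ <- truth$weighted_count[match(fams, truth$family_id)]
  e[is.na(e)] <- 0; t_[is.na(t_)] <- 0
  dev <- abs(e - t_)
  r <- if (length(fams) > 2 && stats::sd(e) > 0 && stats::sd(t_) > 0)
    cor(e, t_) else NA_real_
  structure(list(mean_abs_dev = mean(dev),
                 sd_abs_dev = stats::sd(dev),
                 pearson_r = r,
                 n_families = length(fams),
                 table = data.frame(family_id = fams, estimated = e,
                                    true = t_, abs_dev = dev,
                                    stringsAsFactors = FALSE)),
            class = "ko_deviation")
}

#' @export
print.ko_deviation <- function(x, ...) {
  cat(sprintf("Deviation over %d families: mean |dev| = %.4f (SD %.4f), Pearson r = %.4f\n",
              x$n_families, x$mean_abs_dev, x$sd_abs_dev, x$pearson_r))
  invisible(x)
}

#' Inflation and correction folds
#'
#' Expresses, in units of the baseline deviation, how much spurious
#' peptides inflate the mean absolute deviation
#' (\code{dev_unfiltered / dev_baseline}) and how much of that inflation
#' the filter removes
#' (\code{(dev_unfiltered - dev_filtered) / dev_baseline}).
#'
#' @param dev_unfiltered,dev_filtered,dev_baseline mean absolute
#'   deviations (baseline must be positive).
#' @return A list with \code{inflation_fold} and \code{correction_fold}.
#' @export
fold_correction <- function(dev_unfiltered, dev_filtered, dev_baseline) {
  if (!is.finite(dev_baseline) || dev_baseline <= 0)
    stopf("dev_baseline must be positive")
  list(inflation_fold = dev_unfiltered / dev_baseline,
       correction_fold = (dev_unfiltered - dev_filtered) / dev_baseline)
}

#' The composite family-subset experiment
#'
#' Reproduces the subset protocol used to quantify the filter's effect:
#' sample \code{subset_families} families; restrict the simulation
#' (Type 3) hits to peptides originating from the subset; then, over the
#' full catalog, compare three abundance profiles against the subset's
#' true counts — the subset hits alone (baseline), the subset plus the
#' unknown-protein (Type 2) hits unfiltered, and the same composite with
#' the sparse/low-identity filter applied. Weights are recomputed within
#' each scenario.
#'
#' @param universe a \code{ko_universe}.
#' @param subset_families number of families in the subset.
#' @param type3_hits,type3_peptides hits and truth for the simulation
#'   set.
#' @param type2_hits hits of the unknown-protein peptide set.
#' @param min_hits,min_best_identity,combine the filter
#'   (\code{\link{apply_filter}}).
#' @param allocation abundance allocation mode.
#' @param seed integer seed for the family subset.
#' @return A list of class \code{ko_composite}: the subset family ids,
#'   the three profiles, their \code{\link{deviation_stats}} against the
#'   truth, the \code{\link{fold_correction}} folds, and the filter
#'   report.
#' @export
composite_experiment <- function(universe, subset_families,
                                 type3_hits, type3_peptides, type2_hits,
                                 min_hits = 50L, min_best_identity = 55,
                                 combine = "ALL",
                                 allocation = "PER_HIT", seed = 1L) {
  cat_ <- resolve_catalog(universe)
  subset_families <- assert_count(subset_families, "subset_families")
  if (subset_families > nrow(cat_$families))
    stopf("subset_families (%d) exceeds the catalog size (%d)",
          subset_families, nrow(cat_$families))
  subset <- with_seed(derive_seed(seed, "composite-subset"),
                      sort(sample(cat_$families$family_id, subset_families)))
  keep_pep <- type3_peptides$source_family_id %in% subset
  pep_sub <- type3_peptides[keep_pep, , drop = FALSE]
  hits_sub <- type3_hits[type3_hits$qseqid %in% pep_sub$peptide_id, ,
                         drop = FALSE]
  truth <- true_abundance(pep_sub, universe)

  w_sub <- peptide_weights(hits_sub)
  prof_subset <- weighted_abundance(hits_sub, w_sub, universe, allocation)

  comp <- rbind(as.data.frame(hits_sub), as.data.frame(type2_hits))
  attr(comp, "evalue_max") <- attr(type3_hits, "evalue_max")
  w_comp <- peptide_weights(comp)
  prof_unfiltered <- weighted_abundance(comp, w_comp, universe, allocation)

  flt <- apply_filter(comp, w_comp, min_hits, min_best_identity, combine)
  prof_filtered <- weighted_abundance(flt$hits, flt$weights, universe,
                                      allocation)

  dev_baseline <- deviation_stats(prof_subset, truth)
  dev_unfiltered <- deviation_stats(prof_unfiltered, truth)
  dev_filtered <- deviation_stats(prof_filtered, truth)
  folds <- fold_correction(dev_unfiltered$mean_abs_dev,
                           dev_filtered$mean_abs_dev,
                           dev_baseline$mean_abs_dev)
  structure(list(subset = subset,
                 truth = truth,
                 profiles = list(subset = prof_subset,
                                 unfiltered = prof_unfiltered,
                                 filtered = prof_filtered),
                 deviations = list(baseline = dev_baseline,
                                   unfiltered = dev_unfiltered,
                                   filtered = dev_filtered),
                 folds = folds,
                 filter_report = flt$report,
                 filter_spec = flt$spec,
                 n_type3_peptides = nrow(pep_sub),
                 n_type2_peptides = length(unique(type2_hits$qseqid))),
            class = "ko_composite")
}

#' @export
print.ko_composite <- function(x, ...) {
  cat(sprintf("Composite experiment: %d subset families, %d simulation peptides, %d unknown-set peptides with hits\n",
              length(x$subset), x$n_type3_peptides, x$n_type2_peptides))
  cat(sprintf("  mean |dev|: baseline %.4f, unfiltered %.4f, filtered %.4f\n",
              x$deviations$baseline$mean_abs_dev,
              x$deviations$unfiltered$mean_abs_dev,
              x$deviations$filtered$mean_abs_dev))
  cat(sprintf("  inflation %.2f-fold, correction %.2f-fold\n",
              x$folds$inflation_fold, x$folds$correction_fold))
  invisible(x)
}

#' Write / read an abundance profile TSV
#'
#' Two-section file: settings lines prefixed \code{#} (allocation,
#' peptide counts, NONFAMILY mass), then a header and one row per family
#' (\code{family_id}, \code{weighted_count}, \code{n_peptides}).
#'
#' @param profile a \code{ko_abundance}.
#' @param path file path.
#' @return Invisibly \code{path} (write) or a \code{ko_abundance}
#'   (read).
#' @export
write_abundance <- function(profile, path) {
  hdr <- c(sprintf("# allocation=%s", attr(profile, "allocation")),
           sprintf("# n_peptides_used=%d", attr(profile, "n_peptides_used")),
           sprintf("# nonfamily=%.10g", attr(profile, "nonfamily")))
  body <- sprintf("%s\t%.10g\t%d", profile$family_id,
                  profile$weighted_count, profile$n_peptides)
  writeLines(c(hdr, "family_id\tweighted_count\tn_peptides", body), path)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  body <- lines[!grepl("^#", lines)][-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stopf("'%s': malformed abundance row", path)
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  df <- data.frame(family_id = m[, 1],
                   weighted_count = as.numeric(m[, 2]),
                   n_peptides = as.integer(m[, 3]),
                   stringsAsFactors = FALSE)
  new_abundance(df, nonfamily = as.numeric(get("nonfamily")),
                allocation = get("allocation"),
                n_used = as.integer(get("n_peptides_used")),
                settings = list())
}
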