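# End-to-end orchestration: staged pipeline runs with manifests, and the
# self-contained reproduction of the two acceptance experiments.

#' Calibrated default scoring
#'
#' The package default scoring for searches against the synthetic
#' reference: BLOSUM62, gap open 11 / extend 1, and an effective
#' database size tuned so that peptides from screened unknown proteins
#' reproduce the hit statistics reported for real large-database
#' searches (roughly a third of 31-mers aligning, predominantly 0-10
#' hits each, best identities mostly below 55 percent). See the methods
#' vignette for the calibration.
#'
#' @return A \code{\link{scoring_params}} object.
#' @export
default_scoring <- function() {
  scoring_params(effective_db_residues = 3e6)
}

PIPELINE_STAGES <- c("simulate", "sample", "align", "profile", "abundance")

stage_inputs <- list(simulate = character(0),
                     sample = c("universe/proteins.faa",
                                "universe/mapping.tsv"),
                     align = c("universe/proteins.faa", "universe/mapping.tsv",
                               "peptides.faa", "peptides_truth.tsv"),
                     profile = c("hits.tsv", "peptides_truth.tsv",
                                 "universe/mapping.tsv"),
                     abundance = c("hits.tsv", "peptides_truth.tsv",
                                   "universe/mapping.tsv"))

stage_artifact <- c(simulate = "universe/proteins.faa",
                    sample = "peptides.faa",
                    align = "hits.tsv",
                    profile = "behavior.tsv",
                    abundance = "abundance.tsv")

digest_files <- function(paths) {
  sums <- tools::md5sum(paths)
  paste(sprintf("%s:%s", basename(paths), unname(sums)), collapse = ",")
}

update_manifest <- function(out_dir, stage, inputs, seed, params) {
  path <- file.path(out_dir, "manifest.tsv")
  line <- sprintf("%s\t%s\t%d\t%s", stage,
                  if (length(inputs)) digest_files(inputs) else "-",
                  seed, params)
  lines <- if (file.exists(path)) readLines(path) else character(0)
  keys <- sub("\t.*", "", lines)
  if (stage %in% keys) lines[keys == stage] <- line
  else lines <- c(lines, line)
  ord <- match(sub("\t.*", "", lines), PIPELINE_STAGES)
  writeLines(lines[order(ord)], path)
}

#' Run the staged pipeline
#'
#' Runs the requested stages in dependency order
#' (\code{simulate} builds and writes the universe; \code{sample} draws
#' the simulation peptide set; \code{align} searches it against the
#' reference; \code{profile} writes the per-length behavior table;
#' \code{abundance} writes the frequency-weighted profile and, when the
#' truth is available, the deviation statistics). Every stage writes its
#' artifact under \code{out_dir} and records a manifest line (stage,
#' input digests, seed, parameters); a rerun with an identical
#' configuration reproduces every artifact byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   \code{c("simulate","sample","align","profile","abundance")}.
#' @param seed global seed; per-stage streams are derived from it.
#' @param config universe configuration (\code{\link{universe_config}}).
#' @param scoring scoring parameters (default
#'   \code{\link{default_scoring}}).
#' @param evalue_max alignment significance cutoff.
#' @param member_fraction,peptides_per_protein,peptide_length the
#'   simulation peptide sampling parameters.
#' @param allocation abundance allocation mode.
#' @return Invisibly, the manifest path.
#' @export
run_pipeline <- function(out_dir,
                         stages = PIPELINE_STAGES,
                         seed = 1L,
                         config = universe_config(seed = seed),
                         scoring = default_scoring(),
                         evalue_max = 10,
                         member_fraction = 0.10,
                         peptides_per_protein = c(20L, 40L),
                         peptide_length = 31L,
                         allocation = "PER_HIT") {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(stage) {
    paths <- file.path(out_dir, stage_inputs[[stage]])
    miss <- !file.exists(paths)
    if (any(miss)) {
      prereq <- names(stage_artifact)[match(TRUE, vapply(
        names(stage_artifact), function(s)
          basename(stage_artifact[[s]]) %in% basename(paths[miss]), TRUE))]
      upstream <- PIPELINE_STAGES[seq_len(match(stage, PIPELINE_STAGES) - 1L)]
      first_missing <- upstream[vapply(upstream, function(s)
        !file.exists(file.path(out_dir, stage_artifact[[s]])), TRUE)][1]
      stopf("stage '%s' needs '%s'; run stage '%s' first",
            stage, paths[miss][1],
            if (is.na(first_missing)) "simulate" else first_missing)
    }
    paths
  }
  for (stage in stages) {
    inputs <- need(stage)
    message(sprintf("[pipeline] stage %s", stage))
    switch(stage,
      simulate = {
        u <- build_universe(config)
        write_universe(u, file.path(out_dir, "universe"))
        update_manifest(out_dir, stage, inputs, seed,
                        sprintf("n_families=%d;seed=%d",
                                config$n_families, config$seed))
      },
      sample = {
        u <- read_universe(file.path(out_dir, "universe"))
        peps <- sample_type3(u, member_fraction, peptides_per_protein,
                             peptide_length, derive_seed(seed, "sample"))
        write_peptides(peps, file.path(out_dir, "peptides.faa"),
                       file.path(out_dir, "peptides_truth.tsv"))
        update_manifest(out_dir, stage, inputs, seed,
                        sprintf("member_fraction=%g;per=%s;length=%d",
                                member_fraction,
                                paste(peptides_per_protein, collapse = "-"),
                                peptide_length))
      },
      align = {
        u <- read_universe(file.path(out_dir, "universe"))
        peps <- read_peptides(file.path(out_dir, "peptides.faa"),
                              file.path(out_dir, "peptides_truth.tsv"))
        hits <- search_hits(peps, u, scoring, evalue_max)
        write_outfmt6(hits, file.path(out_dir, "hits.tsv"))
        update_manifest(out_dir, stage, inputs, seed,
                        sprintf("evalue_max=%g;n_eff=%g", evalue_max,
                                if (is.null(scoring$effective_db_residues))
                                  NA_real_ else scoring$effective_db_residues))
      },
      profile = {
        u <- read_universe(file.path(out_dir, "universe"))
        peps <- read_peptides(file.path(out_dir, "peptides.faa"),
                              file.path(out_dir, "peptides_truth.tsv"))
        hits <- read_outfmt6(file.path(out_dir, "hits.tsv"), evalue_max)
        cl <- classify_hits(hits, peps, u)
        tab <- behavior_table(cl, peps)
        write.table(tab, file.path(out_dir, "behavior.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        update_manifest(out_dir, stage, inputs, seed, "include_self=FALSE")
      },
      abundance = {
        u <- read_universe(file.path(out_dir, "universe"))
        peps <- read_peptides(file.path(out_dir, "peptides.faa"),
                              file.path(out_dir, "peptides_truth.tsv"))
        hits <- read_outfmt6(file.path(out_dir, "hits.tsv"), evalue_max)
        w <- peptide_weights(hits)
        prof <- weighted_abundance(hits, w, u, allocation)
        write_abundance(prof, file.path(out_dir, "abundance.tsv"))
        dev <- deviation_stats(prof, true_abundance(peps, u))
        writeLines(sprintf("metric\tvalue\npearson_r\t%.10g\nmean_abs_dev\t%.10g",
                           dev$pearson_r, dev$mean_abs_dev),
                   file.path(out_dir, "metrics.tsv"))
        update_manifest(out_dir, stage, inputs, seed,
                        sprintf("allocation=%s", allocation))
      })
  }
  invisible(file.path(out_dir, "manifest.tsv"))
}

#' Reproduce the simulation-recovery acceptance experiment (t1)
#'
#' Builds the default universe, samples the simulation peptide set
#' (10 percent of members per family, 20-40 distinct 31-mers each),
#' searches it against the full reference at e-value 10, and correlates
#' the frequency-weighted family profile with the true per-family
#' peptide counts.
#'
#' @param seed global seed.
#' @param quiet suppress progress messages.
#' @return A list: \code{pearson_r}, \code{n_families},
#'   \code{n_peptides}, and the underlying profiles.
#' @export
repro_t1 <- function(seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg <- universe_config(seed = derive_seed(seed, "t1-universe"))
  say("[t1] building universe (%d families)", cfg$n_families)
  u <- build_universe(cfg)
  peps <- sample_type3(u, seed = derive_seed(seed, "t1-peptides"))
  say("[t1] sampled %d peptides; searching", nrow(peps))
  hits <- search_hits(peps, u, default_scoring(), evalue_max = 10)
  say("[t1] %d hits; computing profiles", nrow(hits))
  w <- peptide_weights(hits)
  est <- weighted_abundance(hits, w, u, "PER_HIT")
  truth <- true_abundance(peps, u)
  dev <- deviation_stats(est, truth)
  say("[t1] Pearson r = %.5f over %d families", dev$pearson_r,
      dev$n_families)
  list(pearson_r = dev$pearson_r, n_families = dev$n_families,
       n_peptides = nrow(peps), estimated = est, truth = truth,
       deviation = dev)
}

#' Reproduce the filter-correction acceptance experiment (t2)
#'
#' Builds the default universe; derives the unknown-protein peptide set
#' (hypothetical proteins, greedily clustered at 70 percent identity,
#' representatives screened against the reference at 35 percent identity
#' and 70 percent coverage, three 31-mers per retained protein); samples
#' the simulation set; searches both against the full reference; and
#' runs the composite subset experiment (two-thirds of the catalog,
#' unknown-set peptides subsampled to 0.4 per simulation peptide,
#' filter: fewer than 50 hits and best identity below 55 percent).
#'
#' @param seed global seed.
#' @param quiet suppress progress messages.
#' @return The \code{\link{composite_experiment}} result, plus
#'   \code{correction_fold} and \code{inflation_fold} at the top level
#'   and, in \code{$data}, the universe, both peptide sets and both hit
#'   tables (so downstream analyses can reuse them without re-running
#'   the searches).
#' @export
repro_t2 <- function(seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg <- universe_config(seed = derive_seed(seed, "t2-universe"))
  say("[t2] building universe (%d families)", cfg$n_families)
  u <- build_universe(cfg)

  hyp <- hypothetical_proteins(u)
  say("[t2] clustering %d unlabeled proteins", nrow(hyp))
  clus <- greedy_cluster(hyp, 0.70, default_scoring())
  reps <- cluster_representatives(clus, hyp)
  scr <- screen_homology(reps, u, coverage_min = 0.70, identity_min = 0.35,
                         scoring = default_scoring())
  t2_all <- sample_type2(scr$retained, length = 31L, per_protein = 3L,
                         seed = derive_seed(seed, "t2-type2"))

  t3 <- sample_type3(u, seed = derive_seed(seed, "t2-type3"))
  n2 <- min(nrow(t2_all), round(0.4 * nrow(t3)))
  t2 <- with_seed(derive_seed(seed, "t2-subsample"),
                  t2_all[sort(sample.int(nrow(t2_all), n2)), , drop = FALSE])
  say("[t2] %d simulation peptides, %d unknown-set peptides; searching",
      nrow(t3), nrow(t2))
  sc <- default_scoring()
  h3 <- search_hits(t3, u, sc, evalue_max = 10)
  h2 <- search_hits(t2, u, sc, evalue_max = 10)
  say("[t2] hits: %d simulation, %d unknown-set; composite experiment",
      nrow(h3), nrow(h2))
  subset_n <- round(2 / 3 * nrow(u$family_catalog))
  res <- composite_experiment(u, subset_n, h3, t3, h2,
                              min_hits = 50L, min_best_identity = 55,
                              combine = "ALL", seed = derive_seed(seed, "t2"))
  say("[t2] inflation %.2f-fold, correction %.2f-fold",
      res$folds$inflation_fold, res$folds$correction_fold)
  res$correction_fold <- res$folds$correction_fold
  res$inflation_fold <- res$folds$inflation_fold
  res$data <- list(universe = u, type3_peptides = t3, type3_hits = h3,
                   type2_peptides = t2, type2_hits = h2)
  res
}

#' Run an acceptance experiment and print its verdict
#'
#' @param which \code{"t1"} (simulation recovery, threshold Pearson
#'   r >= 0.99) or \code{"t2"} (filter correction, threshold >= 10-fold).
#' @param seed global seed.
#' @param quiet suppress progress messages.
#' @return A list: \code{value}, \code{n}, \code{threshold},
#'   \code{pass}, and the full experiment result in \code{detail}.
#' @export
repro_acceptance <- function(which = c("t1", "t2"), seed = 1L,
                             quiet = FALSE) {
  which <- match.arg(which)
  if (which == "t1") {
    res <- repro_t1(seed, quiet)
    value <- res$pearson_r; n <- res$n_families; thr <- 0.99
    label <- "Pearson r"
  } else {
    res <- repro_t2(seed, quiet)
    value <- res$correction_fold; n <- length(res$subset); thr <- 10
    label <- "correction fold"
  }
  pass <- is.finite(value) && value >= thr
  message(sprintf("[%s] %s = %.4f (threshold %g): %s", which, label,
                  value, thr, if (pass) "PASS" else "FAIL"))
  list(value = value, n = n, threshold = thr, pass = pass, detail = res)
}
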