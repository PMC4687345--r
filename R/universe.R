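# Synthetic protein universe: seeded generation of KO-like families built
# from a shared pool of ancestral domains, plus hypothetical proteins.

#' Configuration for the synthetic protein universe
#'
#' The generator emulates the statistical structure of an orthology
#' reference database: families of homologous proteins with high
#' within-family identity, cross-family domain sharing that yields
#' moderate-identity non-parental alignments with partially shared EC
#' labels, and "hypothetical" proteins with no family membership whose
#' composition matches the family proteins.
#'
#' Each family descends from an ancestor built by concatenating 1-3
#' domain segments joined by random linkers. A domain slot is drawn from
#' the shared ancestral pool with probability \code{domain_share_prob}
#' (so two families can carry diverged copies of the same domain), and is
#' otherwise private to the family. Family members are the ancestor
#' mutated per site at \code{within_family_sub_rate}; shared domain
#' copies are the ancestral segment mutated at
#' \code{cross_family_sub_rate} (> within rate), which produces the
#' moderate-identity cross-family alignments. Substitutions are per-site
#' Bernoulli with uniform replacement over the other 19 residues; no
#' indels are simulated.
#'
#' @param n_families number of families.
#' @param members_per_family integer range \code{c(lo, hi)}; family sizes
#'   are drawn uniformly from it.
#' @param protein_length integer range of protein lengths (residues).
#' @param n_domains size of the shared ancestral domain pool.
#' @param domains_per_family integer range of domain segments per family.
#' @param domain_share_prob probability that a domain slot is filled from
#'   the shared pool rather than a private segment.
#' @param within_family_sub_rate per-site substitution rate from the
#'   family ancestor to each member, in (0,1).
#' @param cross_family_sub_rate per-site substitution rate from an
#'   ancestral pool domain to a family's copy of it; must exceed the
#'   within-family rate.
#' @param n_hypothetical number of hypothetical proteins.
#' @param hypothetical_remnants integer range: how many strongly diverged
#'   domain remnants each hypothetical protein carries. Real unknown-space
#'   proteins retain remote, sub-threshold homology to reference families;
#'   remnants reproduce the moderate-identity, readily filterable hits
#'   that unknown-derived peptides produce against a reference. Use
#'   \code{c(0L, 0L)} for purely random hypothetical proteins.
#' @param hypothetical_remnant_sub_rate per-site substitution rate from a
#'   family's domain segment to a remnant copy; high enough that remnants
#'   stay below homology-screening identity over screening coverage.
#' @param domain_length integer range of domain segment lengths.
#' @param min_peptide_support the longest peptide length the universe
#'   must support; configurations whose minimum protein length cannot
#'   accommodate it are rejected (default 81, the longest standard test
#'   peptide).
#' @param seed integer seed; identical configurations with identical
#'   seeds yield byte-identical universes.
#' @return An object of class \code{ko_config}.
#' @export
universe_config <- function(n_families = 150L,
                            members_per_family = c(5L, 50L),
                            protein_length = c(150L, 600L),
                            n_domains = 40L,
                            domains_per_family = c(1L, 2L),
                            domain_share_prob = 0.03,
                            within_family_sub_rate = 0.05,
                            cross_family_sub_rate = 0.45,
                            n_hypothetical = 2000L,
                            hypothetical_remnants = c(2L, 3L),
                            hypothetical_remnant_sub_rate = 0.58,
                            domain_length = c(40L, 120L),
                            min_peptide_support = 81L,
                            seed = 1L) {
  cfg <- list(
    n_families = assert_count(n_families, "n_families"),
    members_per_family = assert_range(members_per_family, "members_per_family"),
    protein_length = assert_range(protein_length, "protein_length"),
    n_domains = assert_count(n_domains, "n_domains"),
    domains_per_family = assert_range(domains_per_family, "domains_per_family"),
    domain_share_prob = assert_prob(domain_share_prob, "domain_share_prob",
                                    open = FALSE),
    within_family_sub_rate = assert_prob(within_family_sub_rate,
                                         "within_family_sub_rate"),
    cross_family_sub_rate = assert_prob(cross_family_sub_rate,
                                        "cross_family_sub_rate"),
    n_hypothetical = assert_count(n_hypothetical, "n_hypothetical", min = 0L),
    hypothetical_remnants = assert_range(hypothetical_remnants,
                                         "hypothetical_remnants", min = 0L),
    hypothetical_remnant_sub_rate = assert_prob(hypothetical_remnant_sub_rate,
                                                "hypothetical_remnant_sub_rate"),
    domain_length = assert_range(domain_length, "domain_length"),
    min_peptide_support = assert_count(min_peptide_support,
                                       "min_peptide_support", min = 0L),
    seed = assert_count(seed, "seed", min = 0L))
  if (cfg$cross_family_sub_rate <= cfg$within_family_sub_rate)
    stopf("cross_family_sub_rate must exceed within_family_sub_rate")
  structure(cfg, class = "ko_config")
}

#' @export
print.ko_config <- function(x, ...) {
  cat("Synthetic universe configuration\n")
  cat(sprintf("  families: %d (sizes %d-%d), proteins %d-%d aa\n",
              x$n_families, x$members_per_family[1], x$members_per_family[2],
              x$protein_length[1], x$protein_length[2]))
  cat(sprintf("  domain pool: %d, %d-%d per family, share prob %.2f\n",
              x$n_domains, x$domains_per_family[1], x$domains_per_family[2],
              x$domain_share_prob))
  cat(sprintf("  substitution rates: within %.3f, cross %.3f\n",
              x$within_family_sub_rate, x$cross_family_sub_rate))
  cat(sprintf("  hypothetical proteins: %d; seed %d\n",
              x$n_hypothetical, x$seed))
  invisible(x)
}

# Per-site Bernoulli substitution, uniform over the other 19 residues.
# x is an integer vector of codes in 1..20.
mutate_codes <- function(x, rate) {
  hit <- which(runif(length(x)) < rate)
  if (length(hit))
    x[hit] <- ((x[hit] - 1L + sample.int(19L, length(hit), replace = TRUE)) %% 20L) + 1L
  x
}

random_codes <- function(n, prob = AA_BACKGROUND) {
  sample.int(20L, n, replace = TRUE, prob = prob)
}

codes_to_string <- function(x) paste(AA20[x], collapse = "")

#' Build a synthetic protein universe
#'
#' @param config a \code{\link{universe_config}}.
#' @return An object of class \code{ko_universe}: a list with
#'   \code{proteins} (data frame: \code{protein_id}, \code{sequence},
#'   \code{family_id} (\code{NA} for hypothetical proteins), \code{ec}),
#'   \code{family_catalog} (\code{family_id}, \code{ec},
#'   \code{n_members}), \code{domain_map} (\code{domain_id},
#'   \code{sequence}, \code{families}), \code{family_domains}
#'   (per-family domain placements) and the generating \code{config}.
#' @export
build_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "ko_config"))
  if (config$protein_length[1] <= config$min_peptide_support)
    stopf(paste0("protein_length minimum (%d) cannot support peptides of ",
                 "length %d; family ancestors would be too short"),
          config$protein_length[1], config$min_peptide_support)
  with_seed(config$seed, {
    nf <- config$n_families
    family_id <- sprintf("K%05d", seq_len(nf))

    # Shared ancestral domain pool.
    pool_len <- sample_range(config$domain_length, config$n_domains)
    pool <- lapply(pool_len, random_codes)

    # Domain slots per family: shared (pool) or private segments.
    n_slots <- sample_range(config$domains_per_family, nf)
    fam_dom_pool <- vector("list", nf)   # pool index or NA per slot
    fam_dom_seq <- vector("list", nf)    # family copy of each slot
    private <- list()                    # private segments, appended to map
    private_owner <- integer(0)
    for (f in seq_len(nf)) {
      k <- n_slots[f]
      src <- integer(k)
      seqs <- vector("list", k)
      for (s in seq_len(k)) {
        if (runif(1) < config$domain_share_prob) {
          p <- sample.int(config$n_domains, 1L)
          src[s] <- p
          seqs[[s]] <- mutate_codes(pool[[p]], config$cross_family_sub_rate)
        } else {
          len <- sample_range(config$domain_length, 1L)
          seg <- random_codes(len)
          private[[length(private) + 1L]] <- seg
          private_owner <- c(private_owner, f)
          src[s] <- -length(private)
          seqs[[s]] <- seg
        }
      }
      fam_dom_pool[[f]] <- src
      fam_dom_seq[[f]] <- seqs
    }

    # Family ancestors: linker + domain + linker + ... + linker.
    anc <- vector("list", nf)
    fd_rows <- list()
    for (f in seq_len(nf)) {
      seqs <- fam_dom_seq[[f]]
      k <- length(seqs)
      dom_total <- sum(lengths(seqs))
      L <- sample_range(config$protein_length, 1L)
      L <- max(L, dom_total + (k + 1L) * 5L)
      linker_total <- L - dom_total
      cuts <- sort(sample.int(linker_total - (k + 1L) * 2L + 1L, k,
                              replace = TRUE)) + (seq_len(k) * 2L) - 2L
      linker_len <- diff(c(0L, cuts, linker_total))
      parts <- vector("list", 2L * k + 1L)
      pos <- 0L
      for (s in seq_len(k)) {
        parts[[2L * s - 1L]] <- random_codes(linker_len[s])
        pos <- pos + linker_len[s]
        parts[[2L * s]] <- seqs[[s]]
        src <- fam_dom_pool[[f]][s]
        fd_rows[[length(fd_rows) + 1L]] <- data.frame(
          family_id = family_id[f],
          domain_id = if (src > 0) sprintf("D%04d", src)
                      else sprintf("D%04d", config$n_domains - src),
          start = pos + 1L, end = pos + length(seqs[[s]]),
          stringsAsFactors = FALSE)
        pos <- pos + length(seqs[[s]])
      }
      parts[[2L * k + 1L]] <- random_codes(linker_len[k + 1L])
      anc[[f]] <- unlist(parts)
    }

    # Members.
    fam_size <- sample_range(config$members_per_family, nf)
    n_prot <- sum(fam_size)
    prot_seq <- character(n_prot)
    prot_fam <- rep(family_id, fam_size)
    i <- 0L
    for (f in seq_len(nf)) {
      for (m in seq_len(fam_size[f])) {
        i <- i + 1L
        prot_seq[i] <- codes_to_string(
          mutate_codes(anc[[f]], config$within_family_sub_rate))
      }
    }
    protein_id <- sprintf("P%07d", seq_len(n_prot))

    # EC labels: families sharing a pool domain form a graph; EC prefixes
    # shared to a depth that decreases with graph distance (direct sharers
    # agree through level 3, like functionally related orthologs).
    ec <- assign_ec_labels(fam_dom_pool, nf)

    # Hypothetical proteins: i.i.d. draws from the empirical residue
    # composition of the family proteins, plus diverged domain remnants.
    comp <- tabulate(match(strsplit(paste(prot_seq, collapse = ""), "")[[1]],
                           AA20), nbins = 20L)
    comp <- comp / sum(comp)
    nh <- config$n_hypothetical
    hyp_seq <- character(nh)
    if (nh > 0) {
      hyp_len <- sample_range(config$protein_length, nh)
      n_rem <- sample_range(config$hypothetical_remnants, nh)
      for (h in seq_len(nh)) {
        codes <- random_codes(hyp_len[h], prob = comp)
        # Strongly diverged domain remnants: remote homology to a random
        # family, capped at 45% of the protein so homology screening
        # (which requires 70% query coverage) never removes the protein
        # on a single remnant.
        for (r in seq_len(n_rem[h])) {
          f <- sample.int(nf, 1L)
          seg <- fam_dom_seq[[f]][[sample.int(length(fam_dom_seq[[f]]), 1L)]]
          max_len <- min(length(seg), floor(0.45 * hyp_len[h]))
          if (max_len < 20L) next
          flen <- sample.int(max_len - 19L, 1L) + 19L
          fs <- sample.int(length(seg) - flen + 1L, 1L)
          frag <- mutate_codes(seg[fs:(fs + flen - 1L)],
                               config$hypothetical_remnant_sub_rate)
          at <- sample.int(hyp_len[h] - flen + 1L, 1L)
          codes[at:(at + flen - 1L)] <- frag
        }
        hyp_seq[h] <- codes_to_string(codes)
      }
    }

    proteins <- data.frame(
      protein_id = c(protein_id, if (nh > 0) sprintf("H%06d", seq_len(nh))),
      sequence = c(prot_seq, hyp_seq),
      family_id = c(prot_fam, rep(NA_character_, nh)),
      ec = c(ec[match(prot_fam, family_id)], rep(NA_character_, nh)),
      stringsAsFactors = FALSE)

    dom_id <- sprintf("D%04d", seq_len(config$n_domains + length(private)))
    dom_seq <- c(vapply(pool, codes_to_string, ""),
                 vapply(private, codes_to_string, ""))
    carriers <- lapply(seq_along(dom_id), function(d) character(0))
    for (f in seq_len(nf)) {
      for (src in fam_dom_pool[[f]]) {
        d <- if (src > 0) src else config$n_domains - src
        carriers[[d]] <- c(carriers[[d]], family_id[f])
      }
    }
    domain_map <- data.frame(
      domain_id = dom_id, sequence = dom_seq,
      families = vapply(carriers, function(x) paste(unique(x), collapse = ";"), ""),
      stringsAsFactors = FALSE)

    structure(list(
      proteins = proteins,
      family_catalog = data.frame(family_id = family_id, ec = ec,
                                  n_members = fam_size,
                                  stringsAsFactors = FALSE),
      domain_map = domain_map,
      family_domains = do.call(rbind, fd_rows),
      config = config
    ), class = "ko_universe")
  })
}

# EC labels over the family domain-sharing graph: per connected component,
# BFS distance from the component root decides the shared prefix depth
# (d = 1: levels 1-3 shared; d = 2: levels 1-2; d >= 3: level 1). Serial
# numbers are globally unique.
assign_ec_labels <- function(fam_dom_pool, nf) {
  shared <- lapply(fam_dom_pool, function(x) x[x > 0])
  adj <- vector("list", nf)
  pool_users <- split(rep(seq_len(nf), lengths(shared)), unlist(shared))
  for (users in pool_users) {
    users <- unique(users)
    if (length(users) > 1)
      for (u in users) adj[[u]] <- unique(c(adj[[u]], setdiff(users, u)))
  }
  ec <- character(nf)
  visited <- rep(FALSE, nf)
  serial <- 0L
  for (root in seq_len(nf)) {
    if (visited[root]) next
    base <- c(sample.int(6L, 1L), sample.int(20L, 1L), sample.int(30L, 1L))
    dist <- rep(NA_integer_, nf)
    dist[root] <- 0L
    queue <- root
    comp <- root
    visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          dist[v] <- dist[u] + 1L
          queue <- c(queue, v)
          comp <- c(comp, v)
        }
      }
    }
    for (f in comp) {
      serial <- serial + 1L
      d <- dist[f]
      lv <- base
      if (d >= 2L) lv[3] <- sample.int(30L, 1L)
      if (d >= 3L) lv[2] <- sample.int(20L, 1L)
      ec[f] <- paste(c(lv, serial), collapse = ".")
    }
  }
  ec
}

#' @export
print.ko_universe <- function(x, ...) {
  nh <- sum(is.na(x$proteins$family_id))
  cat(sprintf(paste0("Synthetic protein universe: %d proteins in %d families",
                     " + %d hypothetical\n"),
              nrow(x$proteins) - nh, nrow(x$family_catalog), nh))
  cat(sprintf("  total residues: %s; seed %d\n",
              format(sum(nchar(x$proteins$sequence)), big.mark = ","),
              x$config$seed))
  invisible(x)
}

#' Family and hypothetical protein subsets of a universe
#'
#' \code{family_proteins} returns the labeled proteins (the reference
#' searched against); \code{hypothetical_proteins} returns the unlabeled
#' ones.
#'
#' @param universe a \code{ko_universe}.
#' @return A data frame of protein rows.
#' @export
family_proteins <- function(universe) {
  universe$proteins[!is.na(universe$proteins$family_id), , drop = FALSE]
}

#' @rdname family_proteins
#' @export
hypothetical_proteins <- function(universe) {
  universe$proteins[is.na(universe$proteins$family_id), , drop = FALSE]
}

#' Write a universe to a directory
#'
#' Serializes the proteins as 80-column wrapped FASTA, the protein-family-EC
#' mapping as a headerless 3-column TSV (\code{-} for absent values), the
#' domain map and domain placements as TSVs, and the configuration as a
#' flat \code{key=value} file.
#'
#' @param universe a \code{ko_universe}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @seealso \code{\link{read_universe}} for the inverse; reading back a
#'   written universe reproduces every field.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "ko_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(setNames(universe$proteins$sequence,
                                           universe$proteins$protein_id))
  Biostrings::writeXStringSet(seqs, filepath = file.path(dir, "proteins.faa"),
                              width = 80L)
  map <- universe$proteins[, c("protein_id", "family_id", "ec")]
  map$family_id[is.na(map$family_id)] <- "-"
  map$ec[is.na(map$ec)] <- "-"
  write.table(map, file.path(dir, "mapping.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(universe$domain_map, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  write.table(universe$family_domains, file.path(dir, "family_domains.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  cfg <- universe$config
  lines <- vapply(names(unclass(cfg)), function(nm)
    sprintf("%s=%s", nm, paste(cfg[[nm]], collapse = ",")), "")
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a universe from a directory written by \code{write_universe}
#'
#' @param dir directory containing \code{proteins.faa}, \code{mapping.tsv},
#'   \code{domains.tsv}, \code{family_domains.tsv} and \code{config.txt}.
#' @return A \code{ko_universe}.
#' @export
read_universe <- function(dir) {
  faa <- file.path(dir, "proteins.faa")
  if (!file.exists(faa)) stopf("no proteins.faa under '%s'", dir)
  seqs <- Biostrings::readAAStringSet(faa)
  map <- read_mapping_tsv(file.path(dir, "mapping.tsv"))
  if (!identical(names(seqs), map$protein_id))
    stopf("mapping.tsv does not match proteins.faa (ids or order differ)")
  proteins <- data.frame(protein_id = names(seqs),
                         sequence = as.character(seqs),
                         family_id = map$family_id, ec = map$ec,
                         stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  domain_map <- read.table(file.path(dir, "domains.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  family_domains <- read.table(file.path(dir, "family_domains.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  kv <- strsplit(cfg_lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (all(num == floor(num))) as.integer(num) else num
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  config <- do.call(universe_config, vals)
  fam <- proteins[!is.na(proteins$family_id), ]
  catalog <- unique(fam[, c("family_id", "ec")])
  catalog <- catalog[order(catalog$family_id), ]
  catalog$n_members <- as.integer(table(fam$family_id)[catalog$family_id])
  rownames(catalog) <- NULL
  structure(list(proteins = proteins, family_catalog = catalog,
                 domain_map = domain_map, family_domains = family_domains,
                 config = config), class = "ko_universe")
}

# Headerless 3-column mapping TSV; '-' marks absent family/EC. Errors name
# the offending line.
read_mapping_tsv <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stopf("mapping TSV '%s': line %d has %d column(s), expected 3",
          path, bad[1], lengths(parts)[bad[1]])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  data.frame(protein_id = m[, 1],
             family_id = ifelse(m[, 2] == "-", NA_character_, m[, 2]),
             ec = ifelse(m[, 3] == "-", NA_character_, m[, 3]),
             stringsAsFactors = FALSE)
}
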