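# pepko

Frequency-weighted functional profiling of short peptides against
protein-family references, on fully synthetic, seeded data.

Short translated fragments (11–81 residues) align promiscuously:
besides their own ("parental") family they hit related families through
shared domains, and peptides from proteins *outside* the reference
produce sparse, low-identity alignments that inflate naive per-family
counts. `pepko` provides, end to end:

- a **seeded universe generator** — orthologous protein families with
  correlated EC labels, cross-family domain sharing, and unlabeled
  ("hypothetical") proteins carrying diverged domain remnants;
- **peptide set construction** — Type 1 (per-length probes from family
  members), Type 2 (31-mers from hypothetical proteins after greedy
  identity clustering and homology screening), Type 3 (the large
  simulation set: 10 % of members per family, 20–40 distinct 31-mers
  each);
- a built-in **seed-and-extend Smith–Waterman engine** (BLOSUM62,
  affine gaps 11/1) with Karlin–Altschul e-values and byte-stable BLAST
  tabular (outfmt 6) I/O;
- **alignment-behavior profiling** — parental vs non-parental
  statistics per length, family-size identity trends, EC-hierarchy
  similarity of non-parental hits, ROC threshold grids, and a resampled
  length-effect ANOVA;
- the **frequency-weighted abundance estimator** — each peptide's unit
  mass spread 1/N over its N significant hits — with the
  sparse-peptide/low-identity filter (drop peptides with < 50 hits AND
  best identity < 55 %), deviation statistics, and the composite
  family-subset experiment quantifying the filter's correction;
- a staged, manifest-chained **pipeline** with one-command
  reproductions of the two headline experiments.

## Quick start

```r
library(pepko)

# A small universe: 30 families, plus 100 unlabeled proteins.
u <- build_universe(universe_config(n_families = 30L,
                                    n_hypothetical = 100L, seed = 1L))

# The simulation peptide set and its search against the reference.
peps <- sample_type3(u, seed = 1L)
hits <- search_hits(peps, u, default_scoring(), evalue_max = 10)

# Alignment behavior.
cl  <- classify_hits(hits, peps, u)
behavior_table(cl, peps)

# Frequency-weighted abundance vs the truth.
w   <- peptide_weights(hits)
est <- weighted_abundance(hits, w, u)
deviation_stats(est, true_abundance(peps, u))
```

### Staged pipeline

```r
run_pipeline("out", seed = 1L)   # simulate → sample → align → profile → abundance
```

Each stage writes one artifact (`universe/`, `peptides.faa` +
`peptides_truth.tsv`, `hits.tsv`, `behavior.tsv`, `abundance.tsv` +
`metrics.tsv`) and a manifest line with content digests; identical
configurations reproduce every artifact byte for byte. The same stages
are exposed as subcommands of the `inst/scripts/pepko` wrapper
(`simulate-universe`, `sample-peptides`, `align`, `profile`,
`abundance`, `repro`), with a flat key=value config file that any flag
overrides.

## Documentation

- `vignette("pepko-methods")` (source under `vignettes/`) describes the
  generative model, the scoring/e-value calibration, problem sizes and
  known limitations.
- Tests live under `tests/testthat`; `tests/testthat/test-acceptance.R`
  has one block per acceptance criterion.
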