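Package: pepko
Title: Frequency-Weighted Functional Profiling of Short Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the local-alignment behavior of short
    translated metagenomic peptides against protein family references
    (KEGG-Orthology-like families) and for estimating per-family
    abundances with a filter-enabled, frequency-weighted read count.
    Includes a seeded synthetic protein-universe generator emulating
    orthologous families, cross-family domain sharing with correlated
    enzyme-commission labels, and hypothetical proteins; peptide test-set
    construction with greedy identity clustering and homology screening;
    a seed-and-extend Smith-Waterman search engine with Karlin-Altschul
    e-values and BLAST tabular (outfmt 6) interoperability; behavior
    profiling (parental versus non-parental hit statistics, family-size
    identity trends, EC-hierarchy similarity, ROC threshold grids,
    resampled length-effect ANOVA); and the frequency-weighted abundance
    estimator with its sparse-peptide/low-identity filter and deviation
    statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
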