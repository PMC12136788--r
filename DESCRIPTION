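Package: rbnskit
Title: Analysis of RNA Bind-n-Seq and Related RNA-Protein Binding Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for dissecting the RNA-binding specificity of
    multidomain RNA-binding proteins from selection-based sequencing
    assays. Implements kmer enrichment (R values), single-mutant R-drop
    profiles and motif logos for RNA bind-n-seq (RBNS); positional and
    bipartite-spacing enrichment around a locked central motif for
    positional RBNS, including the extra-motif read exclusion filter;
    competition-series normalization and rank-depletion reporting;
    read-to-oligo matching and per-oligo enrichment for designed
    natural-sequence libraries with group comparisons (Kolmogorov-Smirnov,
    Benjamini-Hochberg) and wild-type versus motif-mutant deltas; a
    base-pair-probability engine (builtin partition function or external
    RNAfold) with structure-stratified kmer features and stepwise-AIC
    linear modeling of binding; iCLIP peak centering, merging and overlap
    summaries; single-site equilibrium Kd fitting of fluorescence
    polarization curves; and a seeded synthetic-data generator that
    emulates every assay via an equilibrium occupancy model so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
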