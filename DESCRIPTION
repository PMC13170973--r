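Package: poreSight
Title: Analytics for Nanopore Adaptive-Sampling Sequencing Runs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-run analytics for Oxford Nanopore adaptive-sampling (AS)
    experiments. Filters basecalled reads by criteria evaluated against the
    ONT sequencing summary (channel range, length, Q score, time, pore
    decision), computes per-read and per-taxon mapping and coverage
    statistics into sample manifest files, estimates community genome size
    and sequencing depth reference-free with a bottom-s MinHash sketch of
    canonical k-mers, classifies pore-level read-end reasons into the three
    AS decision classes, and builds comparative test-versus-control reports
    with time-binned decision charts. A deterministic mock-community run
    simulator generates complete synthetic AS datasets (reference, reads,
    sequencing summary, truth alignments) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
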