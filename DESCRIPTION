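Package: zgaenhancers
Title: Chromatin-Based Classification of Enhancers at Zygotic Genome
    Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies open-chromatin regions of early embryos into
    promoter and enhancer elements from multi-mark histone-modification
    coverage (CUT&RUN-style fragment data), culminating in a two-class
    enhancer call that separates H3K4me1-only enhancers from
    H3K4me2-marked enhancers. Implements the region taxonomy
    (promoter/proximal/distal), fragment filtering and spike-in aware
    coverage quantification, enrichment over an IgG control, PCA with an
    SVM reference classifier and discordance-based element calls with a
    coverage-gated rescue rule, a directional-transcription filter for
    cryptic gene TSSs, stage-wise methylation-state and expression
    trajectories, motif/methylation/proximity association statistics, and
    delta-Ct crispant qRT-PCR analysis. A synthetic-data generator plants
    the statistical structure the analysis assumes so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
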