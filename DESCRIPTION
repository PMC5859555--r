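Package: svfusion
Title: Ensemble Fusion of Structural Variant Callsets
Version: 0.2.0
Authors@R: person("svfusion", "developers", role = c("aut", "cre"),
    email = "svfusion@example.org")
Description: Learns an additive group-expectation fusion model from multiple
    structural-variant callers' callsets and a truth set, stratified by SV
    type and size, and applies the model to new samples to produce a single
    merged, filtered, breakpoint-smoothed callset. Includes base-pair Jaccard
    interval metrics, coordinate-space segment projection over a flattened
    genome, expectation-cutoff model fitting, Mantel-test model diagnostics,
    a synthetic multi-caller cohort simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
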