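Package: interscreen
Title: Robust Screening for SNP-by-Exposure and SNP-by-Transcription-Factor
    Interactions in Gene Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate and run interaction-effect screening in
    expression quantitative trait locus (eQTL) studies. Provides a generative
    simulator with exact variance-fraction calibration for outcomes driven by
    a SNP, a (possibly unmeasured) interacting exposure and a tested
    covariate; five interaction-test strategies (standard OLS Wald, HC0 and
    HC3 heteroscedasticity-consistent Wald tests, a median-dichotomized
    exposure model, and a saturated model with quadratic exposure and
    genotype dummies); rank-based inverse normal transformation; evaluation
    metrics (empirical type I error, genomic inflation factor, QQ data,
    per-genotype residual-variance profiles); and a two-step cis-eQTL
    SNP-by-transcription-factor trio screening pipeline with distance and
    marginal-association filters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse,
    yaml,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
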