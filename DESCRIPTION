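Package: fscvsync
Title: Dopamine Terminal Kinetics and Transcript-Function Synchrony Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing ex vivo fast-scan cyclic voltammetry (FSCV)
    recordings of striatal dopamine release together with midbrain gene
    expression. Provides Michaelis-Menten deconvolution of stimulated dopamine
    traces (fixed K_M, estimating per-pulse release and maximal uptake rate),
    four-parameter sigmoid input-output fitting (EA50, span), kappa opioid
    receptor drug-effect and frequency-response metrics, a minimal count-based
    expression stage (filtering, median-of-ratios size factors, a
    Benjamini-Hochberg differential-expression screen, PCA), and the
    rank-pooled transcript-by-function "synchrony" statistic with a
    subject-level permutation test. A seeded synthetic-cohort generator with
    known ground truth makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
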