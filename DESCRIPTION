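Package: omiqc
Title: Pre-Analytical Quality Scoring for Plasma and Serum Proteomics and Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control of blood-derived omics data against pre-analytical
    degradation. Implements a pipeline for combined plasma/serum metabolomics and
    proteomics: detection-limit filtering, generalized-log variance stabilization
    and deterministic left-censored imputation; feature-wise stability statistics
    via empirical-Bayes moderated linear models and per-feature linear mixed
    models with singular-fit fallback; derivation of weighted degradation
    signatures from sitting-time contrasts; and a permutation-normalized
    weighted-mean enrichment score (NES) that rates sample quality and
    blood-cell contamination (erythrocyte, platelet, coagulation). A synthetic
    cohort generator with ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
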