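Package: mc5score
Title: 5mC Regulator-Mediated Molecular Subtyping and Prognostic Scoring for Bulk Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus resampling clustering of tumor samples on the expression of
    the 21 5-methylcytosine (5mC) writer/eraser/reader genes, empirical-Bayes
    moderated differential expression between the resulting clusters, a
    PCA-derived per-sample prognostic "5mC score" with survival-based optimal
    dichotomization, single-sample gene-set enrichment (ssGSEA) of immune and
    therapeutic signatures, and beta-value differential-methylation rules for
    cluster-specific probes and genes. Ships a synthetic cohort generator that
    plants the two-subtype structure the analysis assumes (expression blocks,
    subtype-dependent survival, methylation, mutation rates, and tumor-purity
    confounding) so that every stage of the pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    limma,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
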