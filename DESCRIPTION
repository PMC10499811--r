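Package: lewypanel
Title: CSF Proteomic Biomarker Discovery for Dementia with Lewy Bodies
Version: 0.1.0
Authors@R:
    person("Open", "Contributors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for proximity extension assay
    (PEA/Olink) cerebrospinal-fluid proteomics in a three-group dementia
    cohort (cognitively unimpaired controls, dementia with Lewy bodies,
    Alzheimer's disease). Provides NPX data handling with detectability
    filtering and bridging-sample batch normalization, nested-linear-model
    differential abundance with Benjamini-Hochberg FDR, UpSet-style subset
    partitioning of dysregulated proteins, elastic-net penalized logistic
    panel selection with fold-based stability analysis and ridge refitting,
    ROC/AUC evaluation with bootstrap and repeated cross-validation
    confidence intervals and DeLong paired comparisons, Passing-Bablok
    method-comparison regression for biomarker platform harmonization,
    hypergeometric gene-set enrichment with kappa-similarity term
    clustering, and a synthetic cohort generator with planted ground truth
    so that every stage is testable without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
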