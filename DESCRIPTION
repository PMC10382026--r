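Package: chemosig
Title: Chemotherapy Response Signature Development for Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates chemotherapy response prediction gene
    signatures from labeled expression cohorts. Provides differential
    expression and cluster marker detection, hypergeometric gene-set
    screening with classifier-based predictive filtering, single-sample
    gene-set activity scoring and preranked gene set enrichment analysis,
    a nearest-centroid classifier that emits continuous z-scores calibrated
    to nonresponse probabilities, recursive backward gene elimination that
    maximizes classification AUC, and univariate Cox prognostic screening
    with Kaplan-Meier median-split validation. A synthetic cohort generator
    with planted signal genes and score-linked survival makes the full
    workflow reproducible and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, survival, jsonlite
Suggests: testthat (>= 3.0.0), pROC, fgsea, withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
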