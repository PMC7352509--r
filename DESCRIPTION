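Package: astropair
Title: Patient-Matched Astrocytoma Progression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis workflow for patient-matched initial/recurrent
    astrocytoma pairs: gene-level copy-number profiling and Ward clustering
    with bootstrap stability, cluster-versus-normal moderated differential
    expression with Fisher category enrichment, centroid-correlation
    molecular subtyping (G-CIMP, Verhaak classes), a chromosome-aware
    three-state Gaussian hidden Markov model for per-pair expression-state
    calling with Baum-Welch training and posterior decoding,
    progression-group aggregation of per-pair calls, and shared/private
    somatic-variant summaries. Includes a synthetic patient-matched cohort
    generator with planted ground truth so every stage is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    vcfR,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
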