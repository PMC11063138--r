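Package: csfref
Title: Reference-Protein Adjustment for Cerebrospinal Fluid Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying non-disease inter-individual variability in
    cerebrospinal fluid (CSF) protein concentrations and for adjusting CSF
    biomarkers with data-driven reference proteins. Implements the mean
    standardized CSF protein level, protein embedding and clustering for
    reference-candidate nomination, cross-validated and bootstrap evaluation
    of reference-adjusted logistic biomarker models, AT(N) classification with
    reference-adjusted cutoffs and PET concordance, and partial-correlation,
    ANCOVA and pQTL analyses with and without reference adjustment. A
    synthetic-cohort generator with a planted latent dilution factor provides
    fully ground-truthed data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
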