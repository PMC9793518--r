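Package: archivalgeno
Title: Germline Genotyping Evaluation from Archival-Tissue Low-Coverage WGS
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate germline genotypes imputed from low-coverage
    whole-genome sequencing of archival (FFPE) tissue against blood-derived
    truth, and to carry the resulting scores into outcome models. Includes
    paired-sample dosage concordance (aggregate r-squared in minor-allele
    frequency bins with percentile-bootstrap confidence intervals, stratified
    by imputation quality and copy-number state), polygenic risk scores from
    PGS-Catalog-style weight files, HLA allele concordance at 2- and 4-field
    resolution, copy-number burden and burden-tertile grade imputation, an
    incidence-reweighted Cox proportional-hazards model fitted from first
    principles with Breslow ties and robust (sandwich) variance, Harrell's
    C-index, proportional-hazards diagnostics, Fisher's exact test, and the
    Li-Ji effective number of tests. A synthetic-data module generates every
    input the pipeline consumes so that all stages are testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
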