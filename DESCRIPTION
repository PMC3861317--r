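Package: mechphen
Title: Mechanistic Phenotype Association Testing for Low-Frequency Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates electronic-medical-record ICD-9 diagnosis codes into
    mechanism-level ("mechanistic") phenotypes and tests low minor-allele
    frequency non-synonymous SNPs against them. Provides covariate-adjusted
    additive and recessive logistic models, two reverse-genetics statistics
    that tally minor-allele homozygotes carrying multiply-occurring
    constituent diagnoses (optionally filtered by a one-sided Fisher excess
    test against common-allele homozygotes) with stratified genotype-
    permutation p-values, sequential top-k ontology enrichment with
    Benjamini-Hochberg false-discovery control, simulation studies of
    type-I error and ROC discrimination, and a calibrated synthetic cohort
    generator so the full pipeline runs without protected patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
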