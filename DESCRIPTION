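Package: cfdmr
Title: Marker Discovery from Cell-Free DNA Methylation with Binned
    Average Methylation Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of group-associated differentially methylated
    regions (DMRs) in cell-free DNA methylation data. Computes average
    methylation fractions (AMF) over CpG-dense 100-bp genomic bins from
    per-CpG methylation call files, with conversion-rate and depth quality
    control and blacklist masking. Provides permutation-calibrated
    principal-component selection, a bootstrap-replicated Welch's t-test
    DMR screen with false-discovery-rate control and rank intersection,
    random-forest marker selection with repeated cross-validation and ROC
    evaluation, genomic feature annotation of markers, and comparison of
    marker AMF distributions against external healthy cohorts. Includes a
    fully seeded synthetic-cohort generator so the whole pipeline can be
    exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
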