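Package: ofprofiler
Title: Rare-Variant Genomic Profiling and Subtype Prediction for Ovarian Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of annotated exome variants for ovarian
    failure cohorts: effect-class, reference-frequency and call-quality
    filtering of SnpEff-annotated VCFs; per-variant Fisher exact contrasts
    with conditional maximum-likelihood odds ratios and Benjamini-Hochberg
    FDR control; construction of a disease-associated variant profile
    (variants prevalent in cases and absent from controls); genotype-aware
    Jaccard clustering with Ball/Hartigan cluster-number selection to define
    genomic subtypes; random-forest subtype classification with repeated
    stratified cross-validation, impurity importance and thresholded
    screening of external populations; and a synthetic cohort generator that
    emulates the statistical structure of such a study for testing and
    method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    pROC,
    randomForest,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
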