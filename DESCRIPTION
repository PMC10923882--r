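Package: episig
Title: Discovery and Classification of Blood DNA-Methylation Episignatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A workflow for deriving and applying DNA-methylation
    episignatures from Illumina EPIC-style beta-value matrices: probe
    quality-control filtering, reference-based blood cell-type
    deconvolution, covariate-adjusted per-probe linear modelling with
    empirical-Bayes variance moderation, dual-threshold (FDR and delta-beta)
    signature selection, support-vector-machine probability classification
    of new samples, CpG island/shore and gene-category enrichment, and
    cross-tissue signature comparison. Ships a synthetic-cohort generator
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
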