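Package: molequeen
Title: Skeletal Remodeling and Gene Regulation in Mole-Rat Queens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying the consequences of breeding
    status in cooperatively breeding mole-rats. Implements kinship-aware
    per-gene linear mixed models with permutation-based empirical false
    discovery rates, reference-based cell-type deconvolution with bootstrap
    mediation analysis, Euler characteristic transform featurization of bone
    meshes with weighted support vector machine classification, cross-sectional
    bone geometry with Cox proportional-hazards failure-risk modeling,
    morphometric growth and fecundity models, and promoter/ontology
    enrichment tests. A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    edgeR,
    limma,
    survival,
    e1071,
    pracma,
    jsonlite,
    yaml,
    vcfR,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
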