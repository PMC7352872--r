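Package: ThermoPainAssoc
Title: Machine-Learned Association of Ion-Channel Variants with Thermal
    Pain Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for associating next-generation
    sequencing derived ion-channel gene variants with thermal pain
    sensitivity phenotypes. Discovers pain phenotypes without supervision
    using emergent self-organizing maps with U-matrix watershed
    clustering, validates them with silhouette indices and RIPPER-style
    rule induction, filters variants by an exact Hardy-Weinberg test,
    Shannon information content and chi-squared effect size with
    data-driven computed ABC cutoffs, and quantifies genotype-phenotype
    association with Monte-Carlo resampled random forests audited by
    permutation and negative-control nulls. Includes a synthetic cohort
    generator reproducing the statistical structure the analysis assumes,
    so every stage is testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
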