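Package: epiportrait
Title: Subject-Level Portraits of Statistical Epistasis Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds statistical epistasis networks from case-control genotype
    data by scoring every variant pair with the information gain of its joint
    association with the phenotype, derives a signed per-subject network in
    which each interaction is marked as risk- or protection-enriched for that
    subject's genotype pair, and transforms each connected variant into a
    delta-degree score (negative minus positive incident edges) summarising
    the collective risk impact of its interactions. Includes genotype quality
    control (call rate, minor allele frequency, Hardy-Weinberg equilibrium,
    sample missingness and heterozygosity), leakage-aware cross-validated
    prediction with fold-wise transformation fitting, per-component models,
    an 80/20 holdout protocol, resampling-based feature importance, and a
    penetrance-table simulator with planted two-locus epistasis for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    glmnet,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
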