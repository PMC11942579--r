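Package: BatchHWEP
Title: Batch Quality Consistency from Information Entropy and
    Hardy-Weinberg Equilibrium Population Sizing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates batch-to-batch quality consistency of herbal
    materials by converting dominant-marker (ISSR) band profiles and
    chromatographic fingerprint peak areas into information entropy,
    deriving Hardy-Weinberg equilibrium population (HWEP) sizes and
    minimum sampling quantities (MQS) per batch, cross-validating them by
    leave-one-primer-out and leave-one-peak-out resampling, and
    correlating genetic with chemical heterogeneity by exact small-sample
    Spearman rank correlation. Includes pairwise similarity coefficients
    for binary band matrices with UPGMA clustering and Newick export,
    cosine fingerprint similarity against a mean reference chromatogram,
    and seeded generators for synthetic band matrices and peak tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
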