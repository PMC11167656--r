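Package: dosagenet
Title: Dosage-Aware Gene Co-Expression Network Analysis for Indel Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis for populations
    segregating large chromosomal insertions and deletions (indels), where
    gene dosage acts in cis on expression. Implements count filtering,
    trimmed-mean-of-M-values (TMM) normalization, precision-weighted
    log2-CPM expression and genotype-level coefficients; relative dosage
    scores (RDS) from indel intervals and optional neutralization of
    cis-dosage effects; soft-thresholded correlation networks, topological
    overlap, module detection, eigengenes, module merging and resampling
    stability; module-trait integration (gene significance and module
    membership); hypergeometric GO overrepresentation; and a dosage-QTL
    scan (ANOVA across RDS groups, Tukey post hoc, dosage-response
    slopes). Includes a seeded synthetic-data generator that plants
    modules, cis-dosage effects and trait loadings so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
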