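Package: lgpca
Title: Lineage-Guided Principal Components Analysis for Developmental
    Transcriptome Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical toolkit for multi-organ developmental transcriptome
    atlases. Implements lineage-guided PCA (LgPCA): principal components of a
    quantile-normalized expression matrix weighted by the Abouheif topological
    proximity of samples on a user-defined developmental-lineage tree, with a
    Moran's I decomposition into global (lineage-coherent) and local
    (heterogeneity) axes, extreme-loading gene extraction and rank-sum gene-set
    tests on loadings. Companion modules provide quantile normalization and the
    tissue-specificity index Tau, non-negative matrix factorization metagene
    extraction with consensus-based rank selection (Brunet Kullback-Leibler
    updates), a positional classifier and systematic nomenclature for novel
    long non-coding transcript models relative to a reference annotation,
    neighborhood expression correlation, and seeded synthetic-data generators
    for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
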