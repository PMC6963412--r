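Package: leafGCN
Title: Leaf Transcription-Factor Co-Expression Network Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the transcriptional network that couples
    photosynthesis and leaf development from bulk RNA-seq of leaf samples.
    Implements the construction filters for a curated transcription-factor /
    photosynthesis gene database (genome-hit, protein-completeness, MapMan
    validation and leaf-expression filters), RPKM and log2(x+1) normalization,
    K-means clustering of condition-mean profiles with an a-posteriori
    cluster-number selection rule based on centroid correlations, thresholded
    Pearson gene co-expression networks with joint degree/betweenness/closeness
    hub detection, guilt-by-association mining of developmental genes inside
    expression modules, cross-comparison consistent differential-expression
    intersection, and the chlorophyll-fluorescence, SPAD and malondialdehyde
    leaf-physiology formulas. A negative-binomial count simulator with planted
    anticorrelated expression modules and hub genes makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    igraph,
    jsonlite,
    MASS,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0)
biocViews: Transcriptomics, GeneExpression, Network, Clustering, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
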