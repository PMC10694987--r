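Package: gliopath
Title: Image and Expression Analytics for Glioblastoma Progression
    versus Pseudoprogression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pathology and expression tools for stratifying
    true glioblastoma progression from pseudoprogression. Implements color
    deconvolution of H-DAB and H&E brightfield images with Otsu nucleus
    segmentation, per-cell shape/moment/intensity/texture features, a
    random-forest artifact filter, image-level spatial statistics (k-th
    nearest-neighbour cellularity distance and DAB:hematoxylin pixel
    ratio), UMAP/DBSCAN morphology phenotyping with chi-square
    distribution tests, signature-gene kMeans clustering with
    silhouette-based k selection and permutation cluster validation, and
    cross-platform gene imputation via shared-housekeeping normalization,
    shadow-feature (Boruta-style) predictor selection and random-forest
    regression. Ships ground-truthed synthetic image and expression
    generators so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    RANN,
    uwot,
    Rtsne,
    cluster,
    randomForest,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    png,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Classification, Clustering,
    GeneExpression, ImmunoOncology, Visualization
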