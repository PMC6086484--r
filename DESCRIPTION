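Package: scconvert
Title: Transcriptomic Analysis of Direct Supporting-Cell to Hair-Cell Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for dissecting transcription-factor-driven
    direct cell conversion in the cochlear sensory epithelium from multi-platform
    expression data. Provides depth-harmonized single-cell UMI preprocessing
    (library-size QC, binomial downsampling, blacklist removal, highly variable
    gene selection), PCA/t-SNE embedding with shared-nearest-neighbor modularity
    clustering and marker detection, principal-tree pseudotime along the
    conversion continuum with spline-based pseudotime-dependence tests,
    transcription-factor co-expression networks with modularity communities,
    TMM/FPKM bulk RNA-seq differential expression and cell-type distance metrics,
    single-cell qPCR calibration (dilution-series LOD-Ct, efficiency) and
    quantification, an SVM-based cluster-validation protocol, and conversion-rate
    statistics. A negative-binomial synthetic-data generator emulating the
    supporting-cell to converted-hair-cell continuum makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rtsne,
    e1071,
    igraph,
    limma,
    edgeR,
    jsonlite,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
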