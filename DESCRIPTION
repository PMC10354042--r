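Package: luadgrader
Title: Grading, Segmentation and Heterogeneity Analysis of Lung
    Adenocarcinoma in Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for histological analysis of mouse models of lung
    adenocarcinoma (LUAD) from whole-slide images: Macenko stain
    normalization of H&E slides, construction of an area-balanced 224x224
    patch library from annotated slides, a per-pixel six-class grading
    network (residual encoder with ReLU-only pre-activation, atrous and
    atrous-spatial-pyramid-pooling context layers, transposed-convolution
    decoder) implemented in RcppArmadillo with full backpropagation,
    tumor segmentation with overall-grade assignment by the >=10 percent
    rule, Shannon-diversity intratumor heterogeneity and tumor-burden
    summaries, inter-rater agreement statistics (Cohen's kappa, plain and
    linear-weighted, per-class F1), and co-registration of IHC serial
    sections with a likelihood-ratio G-test for staining enrichment
    across grade regions. Includes deterministic synthetic-slide and
    synthetic-IHC generators so the full pipeline is testable without
    any slide archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    EBImage,
    nnet,
    withr
Config/testthat/edition: 3
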