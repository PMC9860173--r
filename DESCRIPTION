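Package: embryoexpress
Title: Reporter Expression Quantification in Drosophila Embryos and
    Motif Potential of Regulatory Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying reporter gene expression in early
    Drosophila melanogaster embryo images and for assessing the
    regulatory potential of DNA sequences. Provides synthetic
    two-channel embryo renderers and mutagenesis/random-sequence
    library simulators with ground truth; embryo masking, ellipse and
    Feret-diameter axis fitting, and watershed nucleus segmentation;
    normalized anterior-posterior expression profiles with bootstrap
    confidence bands; nucleus-based stripe detection and
    perpendicular width measurement; fixed-ROI germ-layer intensity
    statistics with per-line two-tailed t tests; and position weight
    matrix utilities including Kullback-Leibler information content
    and log-odds scanning with exact dynamic-programming p-values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
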