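Package: fbatox
Title: Single-Cell Image Analysis of Fluorescent Bile Acid Accumulation
    and Hepatocyte Cytotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated image-analysis pipeline for high-content
    fluorescence microscopy of cultured hepatocytes.  Nuclei are segmented
    from the Hoechst channel by spot-enhancing (Laplacian-of-Gaussian) or
    smoothing filters followed by triangle auto-thresholding; per-cell
    fluorescent-anion accumulation is measured in an annular cytosolic
    region of interest extending 3 microns beyond the nuclear border;
    damaged cells and debris are removed by declarative outlier and
    viability rulesets; cell death is called from propidium-iodide
    time-lapse traces; and cytotoxicity is stratified by fluorescent bile
    acid accumulation tertiles.  A synthetic field generator with ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
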