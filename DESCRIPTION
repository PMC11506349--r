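Package: msiStage
Title: Multispectral Histopathology Staging of Cutaneous Squamous Cell
    Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for microscopical
    multispectral imaging (MSI) of hematoxylin and eosin stained skin
    sections, aimed at objective histopathological staging of cutaneous
    squamous cell carcinoma (cSCC). The package reads and writes 13-band
    spectral stacks, averages repeated acquisition frames, corrects
    uneven illumination with a two-dimensional per-pixel gamma map,
    stitches overlapping fields into mosaics by feature matching with
    RANSAC registration, segments collagen/epidermis (520 nm band) and
    lipid droplets/keratin pearls (600 nm band) by adaptive thresholding
    and nuclei (630 nm band) by random-forest pixel classification,
    composes pseudo-color images, and computes staging statistics:
    sliding-window nucleo/cytoplasmic ratios with quality control,
    nuclear-atypia fractions below fixed area thresholds, and keratin
    pearl counts, compared across grades with Student's t-tests and
    ROC/AUC analysis. A synthetic 13-band H&E phantom generator based on
    Beer-Lambert absorption through published hematoxylin and eosin
    spectra provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    ranger,
    tiff,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Classification, Visualization
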