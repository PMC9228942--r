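Package: msiclass
Title: Metabo-Lipidomic Discrimination of Tissue Classes from MALDI Mass
    Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric analysis of MALDI mass spectrometry
    imaging (MSI) data for discriminating pathological from healthy tissue.
    Reads and writes imzML, runs a reproducible spectral preprocessing chain
    (TIC normalization, asymmetric least squares and morphological top-hat
    baseline removal, peak binning, MAD noise gating, pixel-fraction variable
    filtering, log transform, auto-scaling), fits object-level PCA with
    per-pixel score maps, PLS-DA with LDA thresholding, VIP variable
    selection and leave-one-patient-out cross-validation, classifies pixels,
    segments single images by bisecting k-means with Pearson colocalization
    of ions, annotates peaks by formula/adduct mass matching at ppm
    tolerance, and generates synthetic tissue phantoms with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
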