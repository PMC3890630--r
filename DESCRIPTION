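Package: eusbright
Title: Brightness Quantification and Standardization of Endoscopic Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative echogenicity analysis of endoscopic ultrasonography
    (EUS) frames for gastric mesenchymal tumors. Standardizes 8-bit grayscale
    EUS images using the scope's anechoic center and hyperechoic rim as
    brightness anchors, computes region-of-interest brightness statistics
    (mean echogenicity T_mean and heterogeneity T_SD), and classifies lesions
    as GIST versus non-GIST with fixed brightness cutoffs. Includes a
    synthetic phantom and cohort generator with known ground truth, the full
    anchor-extraction chain (histogram equalization, Sobel gradients, edge
    linking, Otsu binarization, grassfire connected-component labeling,
    morphological noise removal), ROC cutoff optimization and diagnostic-test
    metrics with Wilson confidence intervals.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
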