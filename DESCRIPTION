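Package: veinfuse
Title: NIR Hand-Vein Image Enhancement by CLAHE/Fuzzy-Adaptive-Gamma Fusion and Matched-Filter Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Enhancement of low-contrast near-infrared dorsal hand vein images by
    weighted-average fusion of contrast-limited adaptive histogram equalization
    (CLAHE) and a fuzzy adaptive gamma (FAG) operator, followed by vein
    segmentation with a matched filter paired with the first-order derivative
    of Gaussian (MF-FODG). Includes fuzzy histogram hyperbolization and
    adaptive gamma correction baselines, enhancement-quality metrics (MSE,
    PSNR, global SSIM), segmentation metrics (sensitivity, accuracy, Dice),
    an isodata thresholding utility, a seeded generator of synthetic vein
    phantoms with exact ground-truth masks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
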