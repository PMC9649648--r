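Package: hepatoscore
Title: Automated Continuous Kleiner-Brunt Scoring of Liver Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based deep scoring of NAFLD/NASH whole-slide liver histology.
    Four small convolutional classifiers recognize hepatocyte ballooning, lobular
    inflammation, macrovesicular steatosis and fibrosis on a two-scale tile grid;
    per-slide spatial feature maps are aggregated (average class probabilities,
    average weighted class, per-class spatial entropies) and mapped by small
    bounded-output scoring networks to continuous scores on the pathologist's
    Kleiner and Brunt scales, plus the NAFLD activity score. Includes a procedural
    synthetic-histology generator with exact ground truth, a classical
    collagen-area baseline via color deconvolution, and the full ordinal
    evaluation battery (MAE, quadratic weighted Cohen's kappa, support-weighted
    precision/recall/F1).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    EBImage,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
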