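Package: sgpAge
Title: Segmental Greulich-Pyle Bone Age Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated pediatric bone age assessment with segmental
    Greulich-Pyle (GP) fusion. Segments a hand radiograph into short bones,
    carpals and wrist, predicts per-segment and full-hand skeletal ages with
    small convolutional regressors, and fuses them through a convex
    combination whose weight is fitted by a grid sweep against GP-snapped
    ground truth. Includes a synthetic hand-phantom generator with exact
    masks and asynchronous segmental maturity, test-time batch-normalization
    adaptation for domain-shifted images, morphological mask refinement, and
    an agreement-statistics suite (MAD, Bland-Altman, quadratic-weighted
    Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
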