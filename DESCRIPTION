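Package: ecmaf
Title: Electrocardiomatrix Deep-Learning Detection of Brief Atrial Fibrillation Episodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects brief atrial-fibrillation (AF) episodes in long-term ECG
    recordings via the electrocardiomatrix (ECM) representation: ten beat-aligned
    3-second ECG subsegments are stacked and two-section downsampled into a 10x219
    intensity image, classified by a small convolutional neural network trained with
    stochastic gradient descent and combined across three patient-wise splits by
    majority of votes. Layer-wise relevance propagation with the epsilon rule
    explains each decision at pixel level, and detections are scored with
    EC57-style episode and duration statistics, including sensitivity stratified
    by episode duration. A seeded synthetic ECG generator with ground-truth beats
    and rhythm annotations supports desk-scale training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
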