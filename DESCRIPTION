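Package: aquagait
Title: Synchronous Surface EMG and Axial Kinematics Analysis for Equine
    Treadmill and Water-Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing equine walking conditions (overground, dry
    treadmill, water treadmill) from synchronous surface electromyography,
    sacral accelerometry and optical motion capture. Implements IMU-based
    stride segmentation by double integration of sacral vertical acceleration,
    rigid-segment thoracolumbar and pelvic Cardan angles with static
    normalisation, surface-EMG linear-envelope extraction with reference
    voluntary contraction amplitude normalisation, 101-node stride
    time-normalisation, and one-dimensional statistical parametric mapping with
    random-field-theory cluster inference, plus a synthetic session generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
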