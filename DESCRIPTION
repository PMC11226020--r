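Package: pamval
Title: Validation of Automated Acoustic Bird Classifiers and Richness
    Comparison with Point Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate automated acoustic bird classifier output
    (precision, segment-level recall, F-score, and species-specific
    confidence thresholds) and to compare species richness estimated from
    autonomous recording units against in-person point count surveys at
    short and long temporal scales. Includes readers and writers for
    tab-delimited classifier detection tables, confidence-threshold
    filtering, validation-sample and acoustic-segment sampling, species
    accumulation curves, paired t-test comparison tables, and a synthetic
    detection-stream generator with known ground truth so the whole
    pipeline can be exercised and tested without field audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
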