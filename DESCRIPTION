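Package: facedamp
Title: Facial Expression Dampening Analysis Under Elevated Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cardiovascular emotional dampening in the
    production of facial emotional expressions. Provides prototype-based
    classification of FACS Action-Unit codings, accuracy and intensity
    scoring of posed expressions, a five-index inter-rater agreement panel
    between a human coder and an automated coder (percent agreement,
    Cohen's kappa, Gwet's AC1, ordinal Krippendorff's alpha, ICC(3,1)),
    JNC-7 blood-pressure stratification, group-level inference (ANCOVA
    with partial eta squared and Bonferroni subsets, chi-square, partial
    correlation, noncentral-F power analysis), and a synthetic-study
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
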