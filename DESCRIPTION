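Package: tactloc
Title: Quantitative Assessment of Tactile Mislocalization on the Hand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for automated tactile-localization (topesthesia)
    assessments on a schematic hand. Provides a parametric hand template with
    24 stimulation sites, geodesic error metrics constrained to the hand
    outline (distance, offset, spread), confusion matrices and correct
    localization rates, scoring of the Nottingham Sensory Assessment
    localization subscale, distortion-map and confusion-heatmap graphics, and
    a virtual-subject simulator with parametric somatotopic distortion fields
    for generating synthetic assessment sessions with known ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
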