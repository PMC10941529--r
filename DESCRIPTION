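Package: contourfit
Title: Contour Parametrisation and Measurement Reliability for Digitised
    Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning stylus-digitised 3D point clouds of articular
    cartilage contours into a nine-parameter shape description (position,
    orientation, ellipse axis lengths and curvature radius), for building
    anatomical bone coordinate systems from palpated landmarks, for localising
    a fiducial-marker tracked stylus tip (pose fusion and pivot calibration),
    and for assessing intra- and inter-observer reliability of repeated
    digitalisations through variance components, intraclass correlation,
    standard error of measurement and qualitative classification bands.
    Includes a hierarchical synthetic-study generator so every stage can be
    exercised without cadaveric data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
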