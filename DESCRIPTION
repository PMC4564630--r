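Package: fascicle3d
Title: Three-Dimensional Fiber Bundle Architecture of the Supraspinatus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies skeletal muscle fiber bundle (fascicle) architecture from
    serially digitized three-dimensional point data, with the torn supraspinatus as
    the motivating system. Digitized fascicles are reconstructed as interpolating
    centripetal Catmull-Rom splines with arc-length reparameterization; fiber bundle
    length is the spline arc length and lateral/medial pennation angles are measured
    between averaged end tangents and a total-least-squares line of force fitted to
    the intramuscular tendon axis. Includes tendon-tear severity classification and
    caliper-style tear dimension measurement in landmark-derived anatomical planes,
    tie-corrected Mann-Whitney U (asymptotic and exact-enumeration) and
    Kruskal-Wallis tests with Bonferroni-adjusted pairwise comparisons, summary
    tables of median (min-max) architecture per region, part and tear category, a
    seeded synthetic digitized-specimen generator for end-to-end validation, and
    Wavefront OBJ export of reconstructed models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
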