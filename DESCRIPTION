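Package: jawdisp
Title: Two-Track Mandibular Disparity Analysis from Lever Landmarks and
    Discrete Characters
Version: 0.1.0
Authors@R:
    person("Morphology", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes six biomechanical measurements of the vertebrate
    mandible (anterior, posterior and opening mechanical advantage, a
    second-moment-of-area stiffness proxy, length-width ratio, and
    relative triturating-surface width) from named 3D landmarks and
    cross-section ellipse axes; ordinates continuous measurements by
    principal component analysis and discrete character matrices by Gower
    dissimilarity and principal coordinate analysis; and compares group
    disparities via bootstrapped sum-of-variances with two-sided
    Wilcoxon (Mann-Whitney) tests under Bonferroni correction. Includes
    a synthetic-data generator emulating turtle jaw-type archetypes and
    clustered character matrices so the full pipeline is testable
    without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
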