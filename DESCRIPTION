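Package: octaphen
Title: Retinal Microvascular Phenotyping from OCT-Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phenotyping of the retinal superficial vascular
    complex from en-face OCT-angiography scans. Enhances vessels with a
    2-D optimally-oriented-flux filter, binarizes and cleans the response,
    converts masks into centerline graphs with per-point calibers from the
    Euclidean distance transform, and computes a panel of structural and
    hemodynamic-surrogate metrics: regional vessel density, foveal
    avascular zone area, tortuosity, branching-point counts, bifurcation
    distance, mean radius, a Kolmogorov-Smirnov score of deviation from
    Murray's law, and branching symmetry, split into large- and
    small-caliber networks at 20 micrometres. Includes generators for
    synthetic vascular trees with analytic ground truth and for two-eye
    cohort tables, plus generalized estimating equations with exchangeable
    working correlation and cluster-robust errors for eye-level analyses
    clustered by participant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
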