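Package: oildrops
Title: Radial Mapping of Essential-Oil Droplets in Root Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the radial distribution of fluorescent essential-oil
    droplets across entire root cross-sections, as used for valerian
    (Valeriana officinalis) breeding material. Segments droplets from composed
    fluorescence-microscopy slice images (Huang fuzzy-entropy thresholding,
    particle size and circularity filters), extracts the irregular root edge
    contour, normalises every droplet position to a relative center-to-edge
    distance along its polar ray, bins droplets into nine equal-width distance
    classes, computes per-class counts and densities (droplets per square
    millimetre), aggregates by experimental factors, and compares factor
    levels with Friedman, Wilcoxon signed-rank, one-way ANOVA and
    Student-Newman-Keuls procedures. Includes a seeded synthetic slice
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
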