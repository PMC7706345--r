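Package: trenchroot
Title: Root Distribution Phenotyping from Trench-Profile Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies vertical and horizontal root distribution from
    photographs of a trench profile wall. Images are normalized into a
    fixed 60 cm x 60 cm frame, roots are segmented with a U-shaped fully
    convolutional network trained on manually traced masks, and the
    segmented masks are folded about the plant hill, skeletonized and
    summarized as Depth50 and Width50 (the depth and hill distance
    enclosing half of the total root length). Includes validation
    statistics (Dice coefficient, Pearson correlation), diversity
    statistics (broad-sense heritability from variance components,
    one-way ANOVA, Steel-Dwass all-pairs comparison, hierarchical
    clustering of standardized traits) and a seeded generator of
    synthetic trench images with pixel-exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
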