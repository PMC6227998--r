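Package: cspshapes
Title: Clustered Shape Primitives for Binary Colony Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the morphology of two-dimensional binary masks of
    microbial colonies using clustered shape primitives (CSPs): chord-length
    vectors measured at equally spaced angles through every boundary pixel,
    clustered per experimental group by k-means into a learned visual-word
    vocabulary. Provides the three spatial point-pattern indices (radial,
    angular and pair-correlation deviations from complete spatial
    randomness) used as comparator features, normalized CSP histogram
    features, single-feature linear discriminant classification with
    repeated train/test, leave-one-out cross-validation and feature-analysis
    protocols, and a synthetic generator of filamentous colony masks for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
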