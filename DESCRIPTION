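Package: palaeotax
Title: Quantitative Coherence Testing of Cultural Taxonomic Units from
    Lithic Trait and Outline Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the internal coherence of named
    archaeological cultures and their higher-order macro-units from three
    lithic data domains: presence/absence trait matrices for toolkit
    composition and technological organisation, and 2D artefact outlines of
    projectile armatures. Implements elliptic Fourier outline analysis with
    harmonic-power calibration and PCA shape space, Gower dissimilarities on
    tri-state trait data, a permutation-based standardized-effect-size test
    of group coherence, bootstrapped Ward dendrograms with majority-rule
    collapsing and tanglegram comparison, Mantel tests and correlograms over
    geographic distance classes, morphological disparity through time, and
    CART-based trait importance. Ships a seeded synthetic-data generator that
    emulates the regional, chronological and macro-unit structure of a Final
    Palaeolithic/earliest Mesolithic dataset so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    rpart,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
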