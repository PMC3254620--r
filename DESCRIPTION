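Package: unguis
Title: Morphometric Diagnosis of Primate Grooming Claws and Ordered-Character Parsimony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for diagnosing unguis form (nail, claw,
    tegula, grooming claw) on primate distal phalanges and for placing fossil
    primates cladistically. Implements geometric-mean size standardization of
    linear measurements, correlation-matrix principal component analysis,
    single-specimen t-tests against reference group summaries, Tamhane T2 and
    Hotelling pairwise comparisons, pedal-proportion ratio batteries and
    discriminant analysis with jackknife cross-validation, and an
    ordered-character (Wagner) and unordered (Fitch) maximum-parsimony engine
    with exhaustive and branch-and-bound search, ensemble tree statistics
    (tree length, consistency, homoplasy, retention and rescaled consistency
    indices), consensus trees, NEXUS input/output and a character-matrix edit
    layer. Ships seeded synthetic-data generators that emulate the sampling
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    MASS,
    ape
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
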