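Package: olfbulb
Title: Olfactory-Bulb Network Model for Odor-Mixture Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a rate-based mitral-granule cell network of the rodent
    olfactory bulb driven by glomerular activity maps. Converts 2-DG-style
    activity images into a 1805-unit lattice input, generates
    respiration-locked glomerular drive, integrates the coupled
    mitral-granule dynamics with range-limited toroidal connectivity,
    conditions the granule-to-mitral synapses with a Hebbian rule to emulate
    reward training on an odorant mixture, and scores discrimination targets
    with a Pearson-based spatial-pattern dissimilarity index. Includes a
    synthetic glomerular-map generator, replicated experiment orchestration
    over connectivity seeds, connection-radius parameter sweeps, and
    Bonferroni-corrected pairwise statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
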