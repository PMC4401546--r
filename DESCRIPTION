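Package: isarr
Title: Individual Species-Area Relationships for Mapped Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes individual species-area relationship (ISAR) curves --
    the mean number of species within radius r of individuals of a target
    species -- from fully mapped plot censuses, and tests them against
    homogeneous and heterogeneous Poisson null models via Monte Carlo
    simulation envelopes and accumulated-deviation goodness-of-fit rank
    tests. Target species are classified per distance interval as
    accumulators, repellers, or no-effect species. Includes kernel
    estimation of spatially varying intensity surfaces for the
    heterogeneous null, size-stratified (adult/sapling) analyses, and a
    synthetic multispecies community generator with known spatial
    structure (complete spatial randomness, habitat association,
    constructed accumulator/repeller interactions) for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
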