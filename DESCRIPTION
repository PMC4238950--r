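Package: esmspread
Title: Epidemic Spreading Model of Misfolded-Protein Propagation on Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic epidemic spreading model (ESM) of misfolded-protein
    (e.g. amyloid-beta) propagation and deposition across a structural brain
    connectome. Provides connectome containers with effective-distance and
    degree-preserving null models, a delayed stochastic integrator for regional
    deposition probabilities, extreme-value (Gumbel) calibration of regional
    PET signals into deposition probabilities, per-subject parameter estimation
    by trajectory matching with seed-region search, arrival-time and
    hub-vulnerability analyses, and synthetic-data generators so every stage is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    fitdistrplus,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
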