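Package: coralclim
Title: Assemblage-Based Sea-Surface Temperature Transfer Functions for Reef Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs sea-surface temperature (SST) and seasonal temperature
    variability (STV) from gridded reef-coral occurrence assemblages. Occurrence
    records are filtered (depth, symbiosis), binned into 1-degree cells as
    proportional taxon compositions, and calibrated against monthly SST
    climatologies with two transfer-function methods implemented from first
    principles: Imbrie-Kipp style Q-mode factor analysis with varimax rotation,
    and an ensemble of single-hidden-layer feed-forward neural networks with
    median aggregation. Fitted models are projected onto fossil (Last
    Interglacial) assemblages to obtain latitudinal anomaly profiles, with LOESS
    smoothing, 5-degree band means, cross-proxy comparison statistics and
    species-pool sensitivity experiments. A synthetic species-niche world with a
    known imposed anomaly provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    MASS,
    withr
Config/testthat/edition: 3
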