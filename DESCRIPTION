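Package: matewave
Title: Two-Sex Individual-Based Metapopulation Model of Range Expansion
    Through Fragmented Corridor Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit, stage-structured, individual-based
    simulation of metapopulation dynamics and range expansion for a
    short-lived species spreading through a corridor of randomly placed
    single-cell habitat patches. Reproduction follows a harmonic-mean
    mating function with configurable harem size (obligate monogamy to
    polygyny), survival is density dependent in local female numbers,
    and juvenile dispersal uses a stochastic stepwise movement model
    with perceptual range, directional persistence, per-step mortality
    and pluggable settlement rules (habitat-only, mate-search,
    density-dependent, and their combination). Includes factorial
    experiment drivers, range-edge and spread-rate metrics,
    neighbourhood mating-failure summaries, emergent dispersal-kernel
    extraction, LMG relative-importance variance decomposition for the
    factorial output, and a binomial GLM of female mating failure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
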