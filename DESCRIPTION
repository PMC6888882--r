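Package: covarionsim
Title: Memory-Kernel Coevolution Model of Protein Substitution Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates protein sequence divergence under a covarion-style model
    in which the substitution rate of a site is transiently boosted while sites
    in structural contact with it have recently substituted, with an
    exponential memory kernel damping the boost over time. Provides contact-map
    construction from C-alpha coordinates or a synthetic generator, two-branch
    divergence simulations binned by sequence identity, along-chain conditional
    substitution profiles, negative-binomial fits of among-site substitution
    counts, overlap ratios, RMSD-based parameter optimization, and detection of
    spatio-temporal substitution avalanches as connected components of a
    contact/time graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
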