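Package: phagecommons
Title: Phage-Bacteria Delay Dynamics and Pooled-Assay Transgene
    Frequency Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the evolutionary fate of an
    enzyme-producing (public-good) transgenic phage competing with a wild
    phage on free and refuge bacteria in a continuous-flow environment.
    Provides a delay-differential chemostat model with delayed lysis,
    integrated by a fixed-step Euler scheme; competition summaries
    (transgene frequency dynamics, tragedy-of-the-commons outcome
    classification); maximum-likelihood and Bayesian credible-interval
    estimation of transgene frequency from pooled (group-tested) PCR
    plaque assays; and seeded synthetic-data generators for parameter
    recovery and credible-interval coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
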