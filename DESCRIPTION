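Package: abcpower
Title: Power of Approximate Bayesian Computation Model Choice for
    Bottleneck Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for measuring the power of rejection-based
    Approximate Bayesian Computation (ABC) model choice between a standard
    neutral coalescent model and an instantaneous-bottleneck model.  Includes
    a Hudson coalescent-with-recombination simulator with infinite-sites
    mutation, classic site-frequency-spectrum and diversity summary
    statistics (Watterson's theta, nucleotide diversity, Fay and Wu's
    theta_H and H, Tajima's D, haplotype diversity, folded SFS bins),
    rejection sampling with Bayes-factor model choice, local-linear
    regression parameter adjustment, and scenario drivers for power,
    false-positive-rate, tolerance-sweep and estimation-accuracy studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
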