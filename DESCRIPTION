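Package: bdltt
Title: Birth-Death Models of Cladogenesis for Lineage-Through-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transition probabilities and tree likelihoods for the Yule
    process, the constant-rate birth-death process with incomplete sampling,
    and the generalized birth-death process with time-varying rates; the
    pulled-speciation-rate construction mapping any such process onto a
    congruent generalized Yule process (demonstrating non-identifiability
    from lineage-through-time data); closed-form maximum-likelihood
    inference for the identifiable two-epoch Yule model with Fisher
    information and profile intervals; a mass-extinction epoch model; and
    exact simulators for reconstructed trees and speciation-time data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
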