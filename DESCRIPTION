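Package: arbormk
Title: Mk Models, Stochastic Character Mapping and Transition Rates
    Through Time for Mammalian Substrate Preference
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring the evolution of a three-state substrate
    preference character (arboreal, semi-arboreal, nonarboreal) on
    time-calibrated phylogenies. Implements structured Mk models (two-rate,
    ordered four-rate, all-rates-different) and their hidden-rate-class
    expansions with maximum-likelihood fitting and AIC model selection;
    marginal likelihood and Sankoff parsimony ancestral state
    reconstruction; Bayesian stochastic character mapping via
    endpoint-conditioned path sampling (uniformization), with
    summarization across a posterior tree sample by clade matching onto a
    reference tree; and a per-transition-type, branch-length-normalized
    transition-rate-through-time statistic in equal-width time bins.
    Includes a synthetic-data generator (conditioned birth-death trees,
    forward character simulation with optional epoch rate shifts,
    pseudo-posterior tree sets) so every pipeline stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
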