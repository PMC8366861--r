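Package: ssrdemog
Title: Microsatellite Phylogeography and Coalescent-ABC Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mountain-conifer microsatellite phylogeography:
    GENEPOP input/output with EM estimation of null-allele frequencies and a
    locus quality filter; per-population diversity statistics (unbiased gene
    diversity, effective allele number, rarefied allelic and private allelic
    richness, inbreeding coefficient) and an individual-level allele-frequency
    PCA; pairwise Weir-Cockerham F_ST and Slatkin R_ST with an allele-size
    permutation test of phylogeographic signal, isolation-by-distance
    regressions and bootstrapped neighbor-joining population trees; a
    backward-time coalescent simulator for linked chloroplast and unlinked
    nuclear microsatellites under a generalized stepwise mutation model and
    split/admixture/resize demographies; an approximate Bayesian computation
    workflow (reference tables, LDA plus polytomous logistic model choice
    with error calibration, local-linear parameter posteriors with logit
    transformation, theta-ratio population-size-change statistic,
    posterior-predictive checks); cluster-number selection via the Evanno
    delta-K statistic; and an environment-genetics association stage
    (correlation screen with local false discovery rate, variance inflation
    factors, forward stepwise BIC model selection). A synthetic-data module
    generates study-shaped datasets with known truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    ape,
    geosphere,
    MASS,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
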