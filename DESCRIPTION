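Package: driftABC
Title: Temporal Microsatellite Demographic Inference by Serial Coalescent
    Simulation and Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the recent demographic history of populations
    sampled at two or more points in time from microsatellite genotypes.
    Provides Genepop input/output with sampling-time annotations, diversity
    statistics (observed and unbiased expected heterozygosity, rarefied allelic
    richness, Weir-Cockerham F-statistics) with a sample-size-matched
    heterozygosity resampling test, temporal-method effective-population-size
    estimators (Nei-Tajima Fc, Pollak/Waples Fk, and a Wright-Fisher
    pseudo-likelihood), a serial structured-coalescent simulator with stepwise
    mutation under isolation-with-migration-plus-bottleneck and
    secondary-admixture demographies, and approximate Bayesian computation with
    general-linear-model post-adjustment for independently simulated loci,
    including posterior modes, highest-density intervals, Bayes-factor model
    comparison and pseudo-observed-dataset validation. A synthetic-data module
    generates study-shaped datasets (a historical and a modern sample of an
    isolated population plus a large modern outgroup sample) so the entire
    pipeline is exercisable without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
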