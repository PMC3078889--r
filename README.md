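# driftABC

Demographic inference for populations sampled at more than one point in
time, from diploid microsatellite genotypes. The package was built around
the study design of the Cross River gorilla system — a small, isolated
population with a historical (museum) sample taken ~5 generations ago, a
modern sample, and a large modern outgroup population — but every component
is generic for two-deme, two-epoch microsatellite problems.

It answers three questions for such a design:

* **Has diversity changed?** Observed and Nei-unbiased expected
  heterozygosity, rarefied allelic richness, Weir–Cockerham F_IS and F_ST
  with permutation tests, and a sample-size-matched resampling comparison
  of historical vs. modern expected heterozygosity.
* **How small is the population now?** Temporal-method effective-size
  estimators from the variance of allele-frequency change over `t`
  generations: Nei–Tajima `Fc` and Pollak/Waples `Fk` moment estimators
  (sampling plans 1 and 2, chi-square interval estimates) and a
  Wright-Fisher pseudo-likelihood with exact transition matrices for
  `2Ne <= 500`.
* **What is the longer history?** A serial structured-coalescent simulator
  with stepwise mutation under two demographies — isolation-with-migration
  plus a recent exponential bottleneck, versus divergence in isolation with
  a later admixture pulse — drives approximate Bayesian computation with a
  Gaussian linear (GLM) adjustment that treats the K observed loci as
  independent: one simulated locus per parameter draw, per-locus
  likelihoods multiplied. Posterior modes with nested 50/90/95%
  highest-density intervals, Bayes-factor model comparison with a
  retained-count robustness curve, and pseudo-observed-dataset validation
  (coverage, posterior-quantile uniformity, negative controls).

The temporal moment framework is

    Ne = t / (2 [F - 1/(2 S0) - 1/(2 St)])          (plan 2)
    Ne = (t - 2) / (2 [F - 1/(2 S0) - 1/(2 St)])    (plan 1, census ~ Ne)

and the ABC posterior is `prior(theta) * prod_k N(s_k; c + B' phi(theta),
Sigma)` over the K observed loci, with the 6-number per-locus summary
(within-group repeat-length variances for the three sample groups, pairwise
differences in mean repeat length). See `vignettes/methods.Rmd` for the
model, priors, numerics and design decisions.

## Worked example

Everything below is synthetic — the generator reproduces the study design
(14 historical + 71 modern focal individuals, 92 outgroup, 8 loci) from the
published posterior-mode demography:

```r
library(driftABC)
gt <- generateStudyLikeDataset(studyModeParams(), missingRate = 0.05, seed = 2024)
gt
#> GenotypeTable: 177 individuals x 8 loci
#>   crossriver_historical (crossriver, 5 gen BP): 14 individuals
#>   crossriver_modern (crossriver, 0 gen BP): 71 individuals
#>   western_modern (western, 0 gen BP): 92 individuals
#>   missing genotypes: 5.7%

rep2 <- diversityReport(gt, samples = c("crossriver_historical", "crossriver_modern"),
                        nPerm = 999, seed = 1)
rep2$fst; rep2$fstP
#> 0.0071  0.133

pairs <- temporalPairsFromTable(gt, "crossriver_modern", "crossriver_historical")
temporalNe(pairs, method = "waples", plan = 1)
#> NeEstimate (waples, plan 1): Ne = 36.7 [95%: 9.3, 917.0]
pseudoLikelihoodNe(poolRareAlleles(pairs), t = 5)
#> NeEstimate (pseudo-likelihood, plan 1): Ne = 95.8 [95%: 15.6, Inf]

ref <- buildReferenceTable("im", nSims = 50000, seed = 99)   # ~15 s
post <- abcGlmPosterior(ref, observedSummaries(gt, seed = 3), seed = 4)
post
#> PosteriorResult: 9 parameters
#>   two_Nm             mode 5.956  HDI0.95 [1.208, 15.85]
#>   ratio_old_now      mode 39.52  HDI0.95 [1.879, 100]
#>   n_cr_now           mode 215.6  HDI0.95 [92.52, 299.5]
#>   n_ancestral        mode 6961   HDI0.95 [3092, 1.555e+04]
#>   ...
generationsToYears(posteriorMode(post)[["t_divergence"]])
#> 14787
```

The tiny F_ST between the two time points, the wide temporal-`Ne` intervals
at 8 loci, and an IM posterior whose current-size and bottleneck-time modes
sit near the generating values are exactly the behavior the method is
designed to show at this sample size; a single 8-locus dataset identifies
the recent bottleneck far better than the deep divergence time.

Model comparison on the same machinery:

```r
refAdm <- buildReferenceTable("admixture", nSims = 20000, seed = 43)
refIm  <- buildReferenceTable("im",        nSims = 20000, seed = 44)
bayesFactor(refIm, refAdm, observedSummaries(gt, seed = 3))
```

returns the log10 Bayes factor of IM over admixture plus its robustness
curve across retained-simulation counts.

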