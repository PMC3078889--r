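---
title: "Inferring recent demographic history from temporally sampled microsatellites"
author: "driftABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring recent demographic history from temporally sampled microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftABC)
```

# The problem

A small, isolated population (here called the *focal* or "crossriver"
population, after the Cross River gorilla system whose study design the
package emulates) has been genotyped at microsatellite loci twice: a
historical sample taken several generations ago and a modern sample. A
large, related *outgroup* ("western") population has been genotyped once.
Three questions follow:

1. Has genetic diversity changed between the two time points?
2. How small is the focal population's effective size `Ne` over the sampled
   interval?
3. On a longer horizon, did the focal population diverge from the outgroup
   with ongoing gene flow that later ceased (isolation with migration, IM),
   or in isolation followed by a later admixture pulse -- and when did it
   collapse?

The package provides the full chain: Genepop I/O with sampling-time
annotations, diversity statistics, temporal-method `Ne` estimators, a
serial structured-coalescent simulator with stepwise mutation, and
approximate Bayesian computation (ABC) with a Gaussian linear adjustment
and Bayes-factor model choice. A synthetic-data module generates
study-shaped datasets so that every stage is testable without external
data.

# Data model

`GenotypeTable` stores diploid allele calls as repeat counts per individual
and locus, with atomic missingness (never half a genotype) and a sampling
annotation (`label`, `deme`, `time_bp` in generations). Genepop files carry
no time axis, so a plain-text sidecar maps POP blocks, in order, to
annotations. Repeat counts are the unit everywhere;
`repeatsToFragmentLength()` exists but is never applied implicitly, because
fragment-length conventions differ across laboratories while repeat counts
are what the mutation model acts on.

# Diversity statistics

* Observed heterozygosity per locus is the fraction of non-missing
  individuals that are heterozygous; individuals are dropped locus-wise,
  never list-wise.
* Expected heterozygosity uses Nei's unbiased small-sample estimator
  `(n/(n-1)) (1 - sum p_i^2)` with `n` gene copies.
* Allelic richness is the rarefaction expectation
  `sum_i [1 - C(N - N_i, g)/C(N, g)]`; the default rarefaction size `g` is
  the smallest per-locus gene-copy count among the compared samples, so
  every locus supports it.
* `F_IS` and `F_ST` are Weir & Cockerham (1984) estimators; multilocus
  values combine variance components as ratios of sums (the FSTAT
  convention), and the `F_ST` p-value comes from permuting individuals
  between samples with `+1/(n+1)` smoothing, which makes it conservative
  (super-uniform under the null) by construction.
* The sample-size-matched comparison draws, without replacement, as many
  modern individuals as the historical sample contains, recomputes mean
  unbiased expected heterozygosity, and reports the fraction of replicates
  at or above the historical mean. Resampling is without replacement
  because the question is "what would a historical-sized modern sample look
  like", not a bootstrap variance estimate.

# Temporal-method effective size

From two samples of the same population `t` generations apart the package
computes the standardized variance of allele-frequency change per locus:
Nei & Tajima's `Fc` and Pollak's `Fk` (the form used by Waples). The moment
inversion is

```
plan 2:  Ne = t      / (2 [F - 1/(2 S0) - 1/(2 St)])
plan 1:  Ne = (t - 2) / (2 [F - 1/(2 S0) - 1/(2 St)])
```

with `S0`, `St` in diploid individuals. Plan 1 assumes sampling after
reproduction from a population whose census size approximates `Ne` (hence
the `t - 2`); plan 2 assumes sampled individuals do not contribute to the
next generation. A non-positive denominator means all observed change is
explained by sampling and the estimate is `Inf` -- a meaningful outcome,
not an error. 95% bounds follow from chi-square limits on `F` with one
degree of freedom per independent allele.

These statistics are chi-square-like, and alleles expected fewer than ~5
times in a sample destabilize the per-allele denominators (classical
small-expected-count territory). `temporalNe()` therefore pools rare
alleles by default (`poolRareAlleles()`, threshold five expected copies in
the smaller sample); without pooling, `Fc` in particular overestimates `Ne`
by roughly 20% in the package's Wright-Fisher calibration, consistent with
the long-standing observation that moment estimators overestimate `Ne` when
rare alleles abound.

The pseudo-likelihood estimator reduces each locus to biallelic form by
taking every allele in turn as focal versus pooled rest, and computes the
probability of the time-`t` count given the time-0 count by integrating
binomial sampling at both ends over exact Wright-Fisher drift with a
uniform prior on the latent initial frequency. Focal-allele log-likelihoods
are *averaged* within a locus (they reuse the same data) and summed across
loci. Numerics: the transition chain is exact for `2Ne <= 500` and switches
to a cell-integrated normal (diffusion) approximation above, with the
diffusion branch offset so the two agree at the switch point -- without
that splice the small systematic offset between the methods puts a spurious
bump at the boundary of an otherwise flat profile. The point estimate is
the argmax on a log-spaced grid (40 points from 5 to the `Ne`-max, default
3,000); 95% bounds come from the profile at a drop of 1.92 log-units with
log-linear interpolation, the upper bound opening to infinity when the
profile stays flat to the top of the grid.

# Serial coalescent simulator

`simulateLocus()` runs a backward-in-time structured coalescent with two
demes merging into an ancestral population of size `n_ancestral` at
`t_divergence`. The focal population declines exponentially (forward in
time) from `n_cr_now * ratio_old_now` at `t_bottleneck` to `n_cr_now`
today; the outgroup has constant size `n_western`. Serial samples enter the
genealogy at their sampling times. Under IM, lineages migrate symmetrically
at backward rate `two_Nm / (2 N_deme(t))` per lineage during
`[t_migration, t_divergence)` -- `two_Nm` is `2Nm`, so `two_Nm/2` migrant
individuals per generation -- while the admixture model moves each focal
lineage to the outgroup with probability `gamma_admixture` at
`t_admixture_frac * t_divergence` (the admixture-time prior is uniform on
(0,1), which the package reads as a fraction of the divergence time, since
an absolute time below one generation would be meaningless). Time is
continuous; the exponential epoch inverts the integrated coalescence rate
in closed form, with no per-generation discretization. Mutations follow the
strict stepwise model: Poisson(`mu` x branch length) events of +-1 repeat on
a root of 100 repeats. Every downstream summary is invariant under
translation of the root (property-tested), which is why the arbitrary root
value is harmless.

The core loop is implemented in C++ (Rcpp) because reference tables need
tens of thousands of independent genealogies of ~350 lineages; it draws
from R's RNG, so `set.seed()` gives full reproducibility.

Priors follow the study's table: loguniform for `two_Nm` (1-15.85), the
old/now ratio (1-100) and the three times (divergence and migration 10-3162
generations, bottleneck 10-316); uniform for `n_ancestral` (500-25,000);
truncated normals for `n_cr_now` (N(200,100) on [68,300]), `n_western`
(N(24000,5000) on [10000,30000]) and `mu` (N(4e-4,1e-4) on [2e-4,6e-4]);
draws violating `t_migration <= t_divergence` or
`t_bottleneck <= t_divergence` are rejected and redrawn. The probability
mass removed by those constraints (0.44 for IM, 0.70 for admixture, by
quadrature over the loguniform time priors) is restored as a normalization
constant wherever the prior density itself is needed, so Bayes factors
compare properly normalized models.

# ABC with a Gaussian linear adjustment for independent loci

Each simulated locus is summarized by six numbers: within-group variance of
repeat length for the three sample groups and the difference in mean repeat
length for the three group pairs (historical focal, modern focal, outgroup
order). Because loci are independent and exchangeable, the reference table
simulates a *single* locus per parameter draw and the observed dataset's K
loci enter the likelihood as a product -- K-fold cheaper than simulating
whole datasets. Only one haplotype per individual is used when summarizing
diploid data: over-sampling a structured deme inflates early coalescence
(the scattering phase) and mimics a bottleneck, and halving the sample is
the standard guard.

The adjustment works on transformed summaries: variances are strongly
right-skewed, so they enter as `log(1 + var)` (sign-symmetric, so arbitrary
input stays finite); mean differences are symmetric already. After
standardization, the closest `retain_fraction` (default 0.05) of reference
rows by Euclidean distance -- pooled as the mean distance to the K observed
per-locus summaries -- is retained and a multivariate Gaussian linear model
`s = c + B' phi(theta) + e`, `e ~ N(0, Sigma)` is fitted. The basis
`phi(theta)` is the estimation-scale parameter vector (log10 for
loguniform-prior parameters, and also for `n_ancestral`, whose 50-fold
uniform range makes the response log-linear) plus two physically motivated
terms: `log10(mu)` and the expected coalescence depth
`log10(t_divergence + 2 n_ancestral)`. The three pairwise mean differences
are linearly dependent by construction (rank 2), so a rank check drops the
redundant column from the Gaussian model.

The posterior is `prior(theta) x prod_k N(s_obs_k; c + B' phi(theta),
Sigma)`. It is sampled by self-normalized importance sampling from a
defensive mixture of the prior and a Gaussian located by a pilot prior
sample; before the final stage the linear model is *refitted with rows
weighted around the pilot posterior* (a local-likelihood step). This
refit matters: a single straight line across the whole prior range is
mildly but systematically wrong in curved directions -- the ancestral size
above all -- and because the misfit is shared by all K loci of a dataset
while the product treats residuals as independent, the posterior
concentrates on the wrong side. The pseudo-observed-dataset validation
(`validateInference()`) showed exactly the ancestral-size overestimation
that the original study also reported from its own validation; the local
refit removes most of it at desk scale. Remaining small biases
(overestimation of the current focal size, underestimation of deep
divergence times) are visible in the validation report and mirror the
study's published caveats.

Modes and 50/90/95% highest-density intervals come from weighted kernel
densities per parameter on the estimation scale, back-transformed for
reporting. HDIs are shortest contiguous windows of the requested mass on a
512-point grid; near-ties in width (flat densities) resolve toward the
weighted median so that a flat posterior yields a centered interval, and
intervals are expanded minimally so that they nest across levels and always
contain the mode. Reporting uses a generation time of 20 years.

Bayes factors integrate each model's fitted Gaussian likelihood over its
prior by Monte Carlo, with both models' summaries standardized by pooled
statistics so the densities are comparable, and are evaluated at several
retained-simulation counts to give a robustness curve. Model discrimination
from these summaries is genuinely weak when migration is strong and recent
(a large recent admixture pulse mimics near-panmixia), which is why the
packaged model-recovery configuration (`distinguishableIMParams()`) uses
moderate gene flow over a long window, deep divergence and a diverse
ancestral population -- chosen by a pilot distinguishability analysis,
which is what "strong signal" means for a model-choice experiment.

# Synthetic data

`generateStudyLikeDataset()` reproduces the study design -- 14 historical
focal individuals at 5 generations BP, 71 modern focal, 92 modern outgroup,
8 loci -- by simulating `2n` haploid copies per group and pairing
consecutive copies into diploids (exchangeable under the panmictic demes),
with uniform per-genotype missingness on request. It emulates sample sizes,
times and the mutation process, but *not* the error structure of degraded
museum DNA (allelic dropout, null alleles), genotyping artifacts, or
within-population social structure; passing tests therefore validate the
statistical machinery, not robustness to those real-data pathologies.
`generateTemporalWFDataset()` provides forward Wright-Fisher drift with
flat-Dirichlet initial frequencies and non-destructive multinomial sampling
at both endpoints (the plan-2 situation) for calibrating the temporal
estimators.

# Problem sizes and test design

The validation experiments in the test suite and `scripts/acceptance.R`
use sizes chosen as a desk-scale version of the study's own validation:
reference tables of 5x10^4 single-locus simulations for parameter
estimation and 2x10^4 per model for model choice; 20 pseudo-observed
8-locus datasets for coverage and quantile-uniformity checks; 500
Wright-Fisher datasets for moment-estimator calibration; 10,000 replicate
genealogies for coalescence-time checks; 2,000 loci for the
stepwise-mutation equilibrium. Coverage is assessed against the 90% HDI and
quantile uniformity by Kolmogorov-Smirnov at alpha = 0.001; a shuffled-summary
negative control must be rejected.

# Known limitations

* The Gaussian linear adjustment is an approximation; with only 8 loci and
  6 summaries, posteriors for weakly identified parameters (outgroup size,
  migration end time) largely return the prior.
* Bayes factors near zero are expected when the competing histories mimic
  each other; the robustness curve should always be inspected.
* Without rare-allele pooling the Fc moment estimator overestimates `Ne` by
  about 20% under the calibration conditions; pooling is on by default in
  `temporalNe()` but the raw statistics are available unpooled.
* The simulator supports exactly two descendant demes, symmetric migration
  and strict single-step mutation; range constraints and multi-step
  mutations are out of scope.
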