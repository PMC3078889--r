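#' Validate the ABC pipeline on pseudo-observed datasets
#'
#' Draws `nPods` parameter vectors from the prior, simulates a `kLoci`-locus
#' pseudo-observed dataset from each, runs the ABC-GLM posterior against a
#' reference table, and records the posterior quantile of every true
#' parameter. A correctly calibrated pipeline yields uniformly distributed
#' quantiles; the report gives, per parameter, the Kolmogorov-Smirnov
#' p-value of quantile uniformity, the mean signed relative bias of the
#' posterior mode, the fraction of true values inside the 90% HDI, and the
#' number of posterior modes clamped at a prior bound.
#'
#' `shuffleSummaries = TRUE` is a negative control: each pseudo-observed
#' locus' summary entries are randomly permuted before inference, which
#' destroys their meaning and should wreck the calibration.
#'
#' @param refTable a [ReferenceTable-class] for the model being validated
#'   (built once and reused across pods).
#' @param nPods number of pseudo-observed datasets (>= 10).
#' @param kLoci loci per pseudo-observed dataset.
#' @param retainFraction rejection fraction passed to [abcGlmPosterior()].
#' @param nPosterior importance-sample size per pod.
#' @param seed optional integer seed.
#' @param shuffleSummaries negative-control switch (see above).
#' @return List with `report` (data.frame, one row per parameter),
#'   `quantiles` (pods x parameters matrix), `coverage90` (overall fraction
#'   of true values inside their 90% HDI) and `trueParams`.
#' @export
validateInference <- function(refTable, nPods = 20, kLoci = 8,
                              retainFraction = 0.05, nPosterior = 10000,
                              seed = NULL, shuffleSummaries = FALSE) {
  stopifnot(is(refTable, "ReferenceTable"))
  if (nPods < 10) stop("nPods must be >= 10")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  model <- refTable@model
  scheme <- refTable@scheme
  pars <- colnames(refTable@theta)
  d <- length(pars)
  trueP <- samplePrior(nPods, model)
  Q <- matrix(NA_real_, nPods, d, dimnames = list(NULL, pars))
  inHdi <- matrix(NA, nPods, d, dimnames = list(NULL, pars))
  biasRel <- matrix(NA_real_, nPods, d, dimnames = list(NULL, pars))
  clamped <- matrix(FALSE, nPods, d, dimnames = list(NULL, pars))
  support <- priorSupport(model)
  for (i in seq_len(nPods)) {
    loci <- simulateDataset(trueP[i, ], scheme, kLoci = kLoci)
    obs <- t(vapply(loci, perLocusSummaries, numeric(6)))
    if (shuffleSummaries)
      obs <- t(apply(obs, 1, sample))
    post <- abcGlmPosterior(refTable, obs, retainFraction = retainFraction,
                            nPosterior = nPosterior)
    h90 <- posteriorHdi(post, 0.9)
    for (j in seq_len(d)) {
      tv <- trueP[i, pars[j]]
      Q[i, j] <- posteriorQuantile(post, pars[j], tv)
      inHdi[i, j] <- tv >= h90[j, 1] && tv <= h90[j, 2]
      biasRel[i, j] <- (post@mode[pars[j]] - tv) / tv
      gridStep <- diff(support[j, ]) / 511
      mj <- if (post@log10scale[j]) log10(post@mode[pars[j]]) else post@mode[pars[j]]
      clamped[i, j] <- mj <= support[j, 1] + gridStep ||
        mj >= support[j, 2] - gridStep
    }
  }
  report <- data.frame(
    parameter = pars,
    ksP = vapply(seq_len(d), function(j)
      suppressWarnings(ks.test(Q[, j], "punif"))$p.value, numeric(1)),
    meanRelBiasMode = colMeans(biasRel),
    coverage90 = colMeans(inHdi),
    nClampedModes = colSums(clamped))
  list(report = report, quantiles = Q, coverage90 = mean(inHdi),
       trueParams = trueP)
}
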