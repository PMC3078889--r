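#' Sampling schemes for the serial coalescent
#'
#' A sampling scheme lists the haploid sample groups: deme, number of gene
#' copies and sampling time in generations before present. The default is
#' the study design: 14 historical gene copies from the focal population 5
#' generations ago, 71 modern focal copies and 92 modern outgroup copies
#' (one haplotype per sampled individual).
#'
#' @param deme character vector, `"crossriver"` or `"western"`.
#' @param n integer vector of haploid sample sizes (>= 1).
#' @param time numeric vector of sampling times (generations BP, >= 0).
#' @param label group labels.
#' @return A data.frame with columns `label`, `deme`, `n`, `time`.
#' @export
samplingScheme <- function(deme, n, time, label = NULL) {
  stopifnot(all(deme %in% c("crossriver", "western")), all(n >= 1),
            all(time >= 0))
  if (is.null(label)) label <- paste0(deme, "_t", time)
  data.frame(label = label, deme = deme, n = as.integer(n), time = time)
}

#' @rdname samplingScheme
#' @export
defaultSamplingScheme <- function() {
  samplingScheme(deme = c("crossriver", "crossriver", "western"),
                 n = c(14L, 71L, 92L), time = c(5, 0, 0),
                 label = c("crossriver_historical", "crossriver_modern",
                           "western_modern"))
}

paramsToList <- function(params) {
  if (is(params, "IMModelParams")) {
    validObject(params)
    list(model = "im", two_Nm = params@two_Nm, ratio = params@ratio_old_now,
         n_cr_now = params@n_cr_now, n_ancestral = params@n_ancestral,
         n_western = params@n_western, t_div = params@t_divergence,
         t_bot = params@t_bottleneck, t_mig = params@t_migration,
         t_admix = 0, gamma = 0, mu = params@mu)
  } else if (is(params, "AdmixtureModelParams")) {
    validObject(params)
    list(model = "admixture", two_Nm = 0, ratio = params@ratio_old_now,
         n_cr_now = params@n_cr_now, n_ancestral = params@n_ancestral,
         n_western = params@n_western, t_div = params@t_divergence,
         t_bot = params@t_bottleneck, t_mig = 0,
         t_admix = params@t_admixture_frac * params@t_divergence,
         gamma = params@gamma_admixture, mu = params@mu)
  } else if (is.list(params) || is.data.frame(params)) {
    p <- as.list(params)
    if (!is.null(p$t_admixture_frac))
      paramsToList(AdmixtureModelParams(p$ratio_old_now, p$n_cr_now,
                                        p$n_ancestral, p$n_western,
                                        p$t_divergence, p$t_bottleneck,
                                        p$t_admixture_frac, p$gamma_admixture,
                                        p$mu))
    else
      paramsToList(IMModelParams(p$two_Nm, p$ratio_old_now, p$n_cr_now,
                                 p$n_ancestral, p$n_western, p$t_divergence,
                                 p$t_bottleneck, p$t_migration, p$mu))
  } else stop("unsupported parameter object")
}

#' Simulate one microsatellite locus under the serial structured coalescent
#'
#' Backward-in-time structured coalescent with serial sampling: lineages
#' enter at their sampling times; the pairwise coalescence rate is
#' `1/(2 N_deme(t))` per generation; the focal-population size declines
#' exponentially (forward in time) from `n_cr_now * ratio_old_now` at
#' `t_bottleneck` to `n_cr_now` today; the two demes merge into the
#' ancestral population at `t_divergence`. Under the IM model lineages
#' migrate symmetrically at backward rate `two_Nm / (2 N_deme(t))` per
#' lineage during `[t_migration, t_divergence)`; under the admixture model
#' each focal lineage jumps to the outgroup deme with probability
#' `gamma_admixture` at `t_admixture_frac * t_divergence`. Mutations are
#' Poisson(`mu` x branch length) stepwise events (`+-1` repeat, probability
#' 1/2 each) on a root allele of `rootSize` repeats. Time is continuous;
#' the exponential epoch uses closed-form inversion of the integrated
#' coalescence rate, with no per-generation discretization.
#'
#' Uses R's RNG: call `set.seed()` for reproducibility.
#'
#' @param params an [IMModelParams-class], [AdmixtureModelParams-class], or a
#'   named list / one-row data.frame with the corresponding fields.
#' @param scheme a sampling scheme (see [samplingScheme()]).
#' @param rootSize root allele size in repeats. Every downstream summary is
#'   invariant under translation of the root.
#' @param details if `TRUE`, additionally return the coalescence-event times
#'   of the genealogy (generations BP, in event order).
#' @return Named list of integer vectors of allele repeat sizes, one per
#'   sample group, in scheme order; with `details = TRUE`, a list with
#'   elements `alleles` (that list) and `coalTimes`.
#' @export
simulateLocus <- function(params, scheme = defaultSamplingScheme(),
                          rootSize = 100, details = FALSE) {
  p <- paramsToList(params)
  demeCode <- ifelse(scheme$deme == "crossriver", 0L, 1L)
  sampDeme <- rep(demeCode, scheme$n)
  sampTime <- rep(scheme$time, scheme$n)
  res <- .simulateLocusCpp(sampDeme, sampTime, p$n_cr_now, p$ratio,
                           p$n_ancestral, p$n_western, p$t_div, p$t_bot,
                           p$two_Nm, p$t_mig, p$t_admix, p$gamma,
                           if (p$model == "im") 0L else 1L, p$mu,
                           as.integer(rootSize))
  groups <- split(res$alleles, rep(seq_len(nrow(scheme)), scheme$n))[
    as.character(seq_len(nrow(scheme)))] |>
    setNames(scheme$label)
  if (details) list(alleles = groups, coalTimes = res$coal_times) else groups
}

#' Simulate a multi-locus dataset
#'
#' `kLoci` independent calls of [simulateLocus()] under one shared parameter
#' vector (a single mutation-rate draw applies to all loci of a dataset).
#'
#' @inheritParams simulateLocus
#' @param kLoci number of unlinked loci (>= 1).
#' @param seed optional integer seed.
#' @return List of `kLoci` simulated loci.
#' @export
simulateDataset <- function(params, scheme = defaultSamplingScheme(),
                            kLoci = 8, seed = NULL, rootSize = 100) {
  if (kLoci < 1) stop("kLoci must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  lapply(seq_len(kLoci), function(k) simulateLocus(params, scheme, rootSize))
}
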