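#' Build a temporal allele-frequency pair
#'
#' A temporal pair holds, for one locus, the allele frequency vectors at the
#' two sampling times over the union of observed alleles plus the gene-copy
#' counts they were computed from. `x` is the earlier-time-0 sample in the
#' estimator's notation; which real sample plays that role does not matter
#' for the statistics (they are symmetric in `x` and `y`).
#'
#' @param x,y named numeric frequency vectors (names are allele labels); each
#'   must sum to 1. They are aligned on the union of their names, absent
#'   alleles getting frequency 0.
#' @param n0,nt gene copies sampled at each time (>= 2).
#' @return A list with elements `x`, `y` (aligned frequency vectors), `n0`,
#'   `nt`.
#' @export
temporalPair <- function(x, y, n0, nt) {
  if (abs(sum(x) - 1) > 1e-8 || abs(sum(y) - 1) > 1e-8)
    stop("frequency vectors must each sum to 1")
  if (n0 < 2 || nt < 2) stop("gene-copy counts must be >= 2")
  alleles <- union(names(x), names(y))
  if (!length(alleles)) stop("allele names required to align the two samples")
  xa <- setNames(rep(0, length(alleles)), alleles)
  ya <- xa
  xa[names(x)] <- x; ya[names(y)] <- y
  seen <- xa > 0 | ya > 0  # union support = alleles observed in either sample
  if (!any(seen)) stop("no observed allele in either sample")
  list(x = xa[seen], y = ya[seen], n0 = as.integer(n0), nt = as.integer(nt))
}

#' Temporal pairs from a GenotypeTable
#'
#' Convenience constructor: per locus, the allele frequencies of two samples
#' of the same population taken at different times.
#'
#' @param table a [GenotypeTable-class].
#' @param sampleNew,sampleOld sample labels for the time-0 and time-t samples.
#' @return List of temporal pairs, one per locus with data in both samples,
#'   with attribute `t` = difference of the samples' `time_bp`.
#' @export
temporalPairsFromTable <- function(table, sampleNew, sampleOld) {
  afsN <- alleleFrequencies(table, sampleNew)
  afsO <- alleleFrequencies(table, sampleOld)
  ann <- sampleAnnotation(table)
  tElapsed <- abs(ann$time_bp[ann$label == sampleOld] -
                  ann$time_bp[ann$label == sampleNew])
  pairs <- list()
  for (j in seq_along(afsN)) {
    if (is.null(afsN[[j]]) || is.null(afsO[[j]])) next
    pairs[[names(afsN)[j]]] <- temporalPair(afsN[[j]]$freq, afsO[[j]]$freq,
                                            afsN[[j]]$n, afsO[[j]]$n)
  }
  attr(pairs, "t") <- as.integer(tElapsed)
  pairs
}

#' Nei-Tajima standardized variance of allele-frequency change (Fc)
#'
#' Per locus, `Fc = (1/A) * sum_i (x_i - y_i)^2 / ((x_i + y_i)/2 - x_i y_i)`
#' over the `A` alleles of the union support. The multilocus value is the
#' weighted mean of per-locus values with weights equal to the allele counts
#' `A`. Loci monomorphic in both samples are excluded and flagged.
#'
#' @param pairs a list of temporal pairs (see [temporalPair()]); a single
#'   pair is also accepted.
#' @return List with `perLocus`, `multilocus`, `weights` (allele counts) and
#'   `excluded` (names of monomorphic loci).
#' @export
fcStatistic <- function(pairs) {
  pairs <- asPairList(pairs)
  per <- numeric(0); w <- numeric(0); excl <- character(0)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (length(p$x) < 2) { excl <- c(excl, nm); next }
    den <- (p$x + p$y) / 2 - p$x * p$y
    per[nm] <- mean((p$x - p$y)^2 / den)
    w[nm] <- length(p$x)
  }
  list(perLocus = per,
       multilocus = if (length(per)) sum(per * w) / sum(w) else NA_real_,
       weights = w, excluded = excl)
}

#' Pollak/Waples standardized variance of allele-frequency change (Fk)
#'
#' Per locus, `Fk = (1/(A-1)) * sum_i (x_i - y_i)^2 / ((x_i + y_i)/2)`; the
#' multilocus value weights per-locus values by `A - 1` (the number of
#' independent alleles).
#'
#' @inheritParams fcStatistic
#' @return List with `perLocus`, `multilocus`, `weights` (`A - 1`) and
#'   `excluded`.
#' @export
fkStatistic <- function(pairs) {
  pairs <- asPairList(pairs)
  per <- numeric(0); w <- numeric(0); excl <- character(0)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    A <- length(p$x)
    if (A < 2) { excl <- c(excl, nm); next }
    per[nm] <- sum((p$x - p$y)^2 / ((p$x + p$y) / 2)) / (A - 1)
    w[nm] <- A - 1
  }
  list(perLocus = per,
       multilocus = if (length(per)) sum(per * w) / sum(w) else NA_real_,
       weights = w, excluded = excl)
}

#' Pool rare alleles of temporal pairs
#'
#' Temporal F statistics are chi-square-like: alleles observed only a
#' handful of times destabilize the per-allele denominators and bias Fc in
#' particular. Following the usual small-expected-count rule, alleles whose
#' mean frequency across the two samples corresponds to fewer than
#' `minCopies` expected gene copies in the smaller sample are pooled into a
#' single synthetic allele class (only when two or more alleles are rare;
#' pooling never reduces a locus below two classes).
#'
#' @param pairs list of temporal pairs ([temporalPair()]).
#' @param minCopies minimum expected gene copies per allele class.
#' @return The pair list with rare alleles pooled; attributes preserved.
#' @export
poolRareAlleles <- function(pairs, minCopies = 5) {
  single <- !is.null(pairs$x)
  pl <- asPairList(pairs)
  out <- lapply(pl, function(p) {
    thr <- minCopies / min(p$n0, p$nt)
    rare <- (p$x + p$y) / 2 < thr
    if (sum(rare) > 1) {
      x <- c(p$x[!rare], pooled = unname(sum(p$x[rare])))
      y <- c(p$y[!rare], pooled = unname(sum(p$y[rare])))
      if (length(x) >= 2)
        return(list(x = x, y = y, n0 = p$n0, nt = p$nt))
    }
    p
  })
  attr(out, "t") <- attr(pairs, "t")
  if (single) out[[1]] else out
}

asPairList <- function(pairs) {
  if (!is.null(pairs$x)) pairs <- list(locus1 = pairs)
  if (is.null(names(pairs)))
    names(pairs) <- paste0("locus", seq_along(pairs))
  pairs
}

#' Effective size from a temporal F statistic
#'
#' Moment inversion of the expected standardized variance of
#' allele-frequency change. With sample sizes `S0`, `St` in diploid
#' individuals and `t` generations elapsed:
#' plan 2 gives `Ne = t / (2 (F - 1/(2 S0) - 1/(2 St)))`; plan 1, under the
#' assumption that the census size approximates the effective size, gives
#' `Ne = (t - 2) / (2 (F - 1/(2 S0) - 1/(2 St)))`. A non-positive denominator
#' (all observed change explained by sampling) yields `Inf`.
#'
#' 95% bounds follow from chi-square limits on `F` with `df` degrees of
#' freedom (the total number of independent alleles, `sum(A_locus - 1)`):
#' `F` in `[df * F / qchisq(.975, df), df * F / qchisq(.025, df)]`, each limit
#' pushed through the same inversion. The upper `Ne` bound is `Inf` whenever
#' the lower `F` limit does not exceed the sampling term.
#'
#' @param F multilocus temporal F value (> 0).
#' @param S0,St sample sizes in diploid individuals.
#' @param t generations elapsed between the samples (plan 1 needs `t > 2`).
#' @param plan sampling plan, 1 or 2: plan 1 assumes sampling after
#'   reproduction from a population whose census size approximates `Ne`;
#'   plan 2 assumes sampled individuals do not contribute to the next
#'   generation.
#' @param df degrees of freedom for the bounds; `NULL` skips interval
#'   estimation (`NA` bounds).
#' @param method label stored in the result.
#' @return An [NeEstimate-class].
#' @examples
#' neFromTemporalF(0.25, 50, 50, t = 5, plan = 2, df = 40)
#' @export
neFromTemporalF <- function(F, S0, St, t, plan = 2, df = NULL,
                            method = "temporal-F") {
  if (F <= 0) stop("F must be positive")
  plan <- as.integer(plan)
  if (!plan %in% c(1L, 2L)) stop("plan must be 1 or 2")
  if (plan == 1L && t <= 2)
    stop("plan 1 estimator undefined for t <= 2 generations")
  samplingTerm <- 1 / (2 * S0) + 1 / (2 * St)
  numer <- if (plan == 1L) t - 2 else t
  invert <- function(f) {
    den <- 2 * (f - samplingTerm)
    if (den <= 0) Inf else numer / den
  }
  point <- invert(F)
  lower <- upper <- NA_real_
  if (!is.null(df) && is.finite(df) && df >= 1) {
    fHi <- df * F / qchisq(0.025, df)  # upper limit on F -> lower Ne
    fLo <- df * F / qchisq(0.975, df)
    lower <- invert(fHi)
    upper <- invert(fLo)
  }
  NeEstimate(point, lower, upper, method = method, plan = plan,
             details = list(F = F, samplingTerm = samplingTerm, df = df,
                            t = t, S0 = S0, St = St))
}

#' Temporal-method Ne from a set of temporal pairs
#'
#' Computes the multilocus Fc (Nei-Tajima) or Fk (Pollak/Waples) statistic
#' and inverts it to an effective-size estimate with chi-square bounds.
#' Per-locus sample sizes are combined by their harmonic mean (in diploid
#' individuals, i.e. half the gene-copy counts of the pairs).
#'
#' @param pairs list of temporal pairs ([temporalPair()] /
#'   [temporalPairsFromTable()]).
#' @param t generations elapsed (default: the `t` attribute of `pairs`).
#' @param method `"nei-tajima"` (Fc) or `"waples"` (Fk).
#' @param plan sampling plan, 1 or 2.
#' @param poolRare pool rare alleles first (see [poolRareAlleles()]).
#' @return An [NeEstimate-class].
#' @export
temporalNe <- function(pairs, t = attr(pairs, "t"),
                       method = c("nei-tajima", "waples"), plan = 1,
                       poolRare = TRUE) {
  method <- match.arg(method)
  pairs <- asPairList(pairs)
  if (poolRare) pairs <- poolRareAlleles(pairs)
  fres <- if (method == "nei-tajima") fcStatistic(pairs) else fkStatistic(pairs)
  used <- names(fres$perLocus)
  if (!length(used)) stop("no polymorphic locus available")
  hmean <- function(v) length(v) / sum(1 / v)
  S0 <- hmean(vapply(pairs[used], function(p) p$n0 / 2, numeric(1)))
  St <- hmean(vapply(pairs[used], function(p) p$nt / 2, numeric(1)))
  df <- sum(vapply(pairs[used], function(p) length(p$x) - 1, numeric(1)))
  neFromTemporalF(fres$multilocus, S0, St, t = t, plan = plan, df = df,
                  method = method)
}
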