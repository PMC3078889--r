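#' Observed heterozygosity
#'
#' Per locus, the fraction of non-missing individuals that are heterozygous;
#' the mean across loci is unweighted. Loci with no data are excluded from the
#' mean and flagged `NA` per locus.
#'
#' @param table a [GenotypeTable-class].
#' @param sample a sample label.
#' @return List with `perLocus` (named numeric) and `mean`.
#' @export
observedHeterozygosity <- function(table, sample) {
  stopifnot(is(table, "GenotypeTable"))
  keep <- table@pop == sample
  a1 <- table@a1[keep, , drop = FALSE]
  a2 <- table@a2[keep, , drop = FALSE]
  het <- colMeans(a1 != a2, na.rm = TRUE)
  het[colSums(!is.na(a1)) == 0] <- NA_real_
  names(het) <- table@loci
  list(perLocus = het, mean = mean(het, na.rm = TRUE))
}

#' Unbiased expected heterozygosity (Nei)
#'
#' Nei's small-sample unbiased estimator `(n/(n-1)) * (1 - sum(p_i^2))` with
#' `n` the number of gene copies the frequencies were computed from. Loci with
#' fewer than 2 gene copies are undefined and flagged `NA`.
#'
#' @param afs an allele-frequency spectrum as returned by
#'   [alleleFrequencies()].
#' @return List with `perLocus` (named numeric) and `mean`.
#' @export
unbiasedExpectedHeterozygosity <- function(afs) {
  he <- vapply(afs, function(a) {
    if (is.null(a) || a$n < 2) return(NA_real_)
    a$n / (a$n - 1) * (1 - sum(a$freq^2))
  }, numeric(1))
  list(perLocus = he, mean = mean(he, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `sum_i [1 - choose(N - N_i, g)/choose(N, g)]` over alleles with
#' count `N_i` out of `N` total copies. At `g = N` this is exactly the
#' observed allele count; it is monotone non-decreasing in `g`.
#'
#' @param counts named integer vector of allele counts at one locus.
#' @param g rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @param locus optional locus name for error messages.
#' @return Numeric allelic richness (>= 1 whenever data are present).
#' @examples
#' allelicRichness(c(a = 2, b = 2), 2)  # 5/3
#' @export
allelicRichness <- function(counts, g, locus = NULL) {
  N <- sum(counts)
  if (g < 1 || g > N)
    stop("rarefaction size g = ", g, " out of range for locus ",
         if (is.null(locus)) "(unnamed)" else locus, " with ", N, " gene copies")
  # lchoose is 0-safe: choose(N - Ni, g) = 0 when N - Ni < g
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Allelic richness across loci of a sample
#'
#' @param table a [GenotypeTable-class].
#' @param sample a sample label.
#' @param g rarefaction size in gene copies; default is the smallest per-locus
#'   gene-copy count across the loci with data (so every locus supports it).
#' @return List with `perLocus`, `mean` and the `g` used.
#' @export
allelicRichnessTable <- function(table, sample, g = NULL) {
  counts <- alleleCounts(table, sample)
  ns <- vapply(counts, function(x) if (is.null(x)) NA_integer_ else sum(x),
               integer(1))
  if (is.null(g)) g <- min(ns, na.rm = TRUE)
  ar <- vapply(seq_along(counts), function(j) {
    if (is.null(counts[[j]])) return(NA_real_)
    allelicRichness(counts[[j]], g, locus = names(counts)[j])
  }, numeric(1))
  names(ar) <- names(counts)
  list(perLocus = ar, mean = mean(ar, na.rm = TRUE), g = g)
}

#' Sample-size-matched expected-heterozygosity resampling test
#'
#' Draws (without replacement) as many individuals from the modern sample as
#' the historical sample contains, computes the mean unbiased expected
#' heterozygosity across loci, repeats `reps` times, and returns the fraction
#' of replicates whose mean is greater than or equal to the historical mean.
#' A small fraction indicates that the historical sample is more diverse than
#' a size-matched modern sample almost ever is.
#'
#' @param modern a [GenotypeTable-class] with a single population sample (or
#'   the sample to draw from identified by `modernSample`).
#' @param historical a [GenotypeTable-class] holding the historical sample.
#' @param reps number of resampling replicates (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param modernSample,historicalSample sample labels; default the first
#'   label of each table.
#' @return List with `fraction`, the historical mean `heHistorical`, and the
#'   vector `heResampled` of resampled means.
#' @export
heResamplingTest <- function(modern, historical, reps = 10000, seed = NULL,
                             modernSample = sampleLabels(modern)[1],
                             historicalSample = sampleLabels(historical)[1]) {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  histT <- bySample(historical, historicalSample)
  modT <- bySample(modern, modernSample)
  nHist <- nIndividuals(histT)
  nMod <- nIndividuals(modT)
  if (nMod < nHist)
    stop("modern sample (", nMod, ") smaller than historical (", nHist, ")")
  heHist <- unbiasedExpectedHeterozygosity(
    alleleFrequencies(histT, historicalSample))$mean
  res <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(nMod, nHist)
    meanHeOfRows(modT, idx)
  }, numeric(1))
  list(fraction = mean(res >= heHist), heHistorical = heHist,
       heResampled = res)
}

# mean unbiased He across loci for a row subset of a single-sample table
meanHeOfRows <- function(table, idx) {
  a1 <- table@a1[idx, , drop = FALSE]
  a2 <- table@a2[idx, , drop = FALSE]
  he <- vapply(seq_len(ncol(a1)), function(j) {
    copies <- c(a1[, j], a2[, j])
    copies <- copies[!is.na(copies)]
    n <- length(copies)
    if (n < 2) return(NA_real_)
    p <- tabulate(match(copies, unique(copies))) / n
    n / (n - 1) * (1 - sum(p^2))
  }, numeric(1))
  mean(he, na.rm = TRUE)
}

#' Combined diversity report for one or two samples
#'
#' Assembles observed and unbiased expected heterozygosity, rarefied allelic
#' richness and Weir-Cockerham F_IS per sample, plus (when two samples are
#' given) the pairwise Weir-Cockerham F_ST with its permutation p-value.
#'
#' @param table a [GenotypeTable-class].
#' @param samples one or two sample labels (default: all labels, first two).
#' @param g rarefaction size; default the smallest per-locus gene-copy count
#'   across the compared samples.
#' @param nPerm permutations for the F_ST test.
#' @param seed optional seed for the permutation test.
#' @return A list with per-sample data.frames and, for two samples, `fst` and
#'   `fstP`.
#' @export
diversityReport <- function(table, samples = sampleLabels(table), g = NULL,
                            nPerm = 1000, seed = NULL) {
  samples <- samples[seq_len(min(2, length(samples)))]
  if (is.null(g)) {
    ns <- unlist(lapply(samples, function(s) {
      vapply(alleleFrequencies(table, s),
             function(a) if (is.null(a)) NA_integer_ else a$n, integer(1))
    }))
    g <- min(ns, na.rm = TRUE)
  }
  perSample <- lapply(samples, function(s) {
    ho <- observedHeterozygosity(table, s)
    he <- unbiasedExpectedHeterozygosity(alleleFrequencies(table, s))
    ar <- allelicRichnessTable(table, s, g = g)
    fi <- fIS(table, s)
    data.frame(locus = c(table@loci, "mean"),
               Ho = c(ho$perLocus, ho$mean),
               He = c(he$perLocus, he$mean),
               AR = c(ar$perLocus, ar$mean),
               Fis = c(fi$perLocus, fi$multilocus))
  })
  names(perSample) <- samples
  out <- list(samples = perSample, g = g)
  if (length(samples) == 2) {
    f <- fST(table, samples[1], samples[2], nPerm = nPerm, seed = seed)
    out$fst <- f$theta
    out$fstP <- f$p
  }
  out
}
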