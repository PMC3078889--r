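#' Per-locus summary statistics
#'
#' The 6-number summary vector of one locus over the three sample groups:
#' the within-group variance of repeat length for each group, and the
#' difference in mean repeat length for each group pair, in fixed group
#' order (historical focal, modern focal, modern outgroup):
#' `d12 = mean(g1) - mean(g2)`, `d13`, `d23`. All entries are invariant
#' under a global translation of allele sizes.
#'
#' @param locus named list of integer allele vectors, one per sample group in
#'   scheme order (as returned by [simulateLocus()]); `NA` entries are
#'   dropped.
#' @param scheme the sampling scheme (only group count and order are used).
#' @return Named numeric vector of length 6: `var_1..var_3`,
#'   `dmean_12`, `dmean_13`, `dmean_23`. Groups with fewer than 2 observed
#'   alleles yield `NA` (flagged) entries.
#' @examples
#' perLocusSummaries(list(a = c(10L, 12L), b = c(11L, 11L, 14L),
#'                        c = c(9L, 13L)))
#' @export
perLocusSummaries <- function(locus, scheme = NULL) {
  g <- lapply(locus, function(v) v[!is.na(v)])
  if (length(g) != 3)
    stop("exactly 3 sample groups expected, got ", length(g))
  empty <- vapply(g, length, integer(1)) == 0
  if (any(empty))
    stop("group ", names(g)[which(empty)[1]], " has no observed allele")
  v <- vapply(g, function(x) if (length(x) < 2) NA_real_ else var(x), numeric(1))
  m <- vapply(g, mean, numeric(1))
  out <- c(v, m[1] - m[2], m[1] - m[3], m[2] - m[3])
  names(out) <- c("var_1", "var_2", "var_3", "dmean_12", "dmean_13", "dmean_23")
  out
}

# vectorized summaries over a matrix of simulated loci (rows = simulations,
# columns = haploid samples in scheme order)
summariesFromMatrix <- function(X, groupSizes) {
  stopifnot(ncol(X) == sum(groupSizes))
  idx <- split(seq_len(ncol(X)), rep(seq_along(groupSizes), groupSizes))
  ms <- vs <- matrix(0, nrow(X), length(groupSizes))
  for (gi in seq_along(idx)) {
    Xi <- X[, idx[[gi]], drop = FALSE]
    n <- length(idx[[gi]])
    m <- rowMeans(Xi)
    ms[, gi] <- m
    vs[, gi] <- (rowSums(Xi^2) - n * m^2) / (n - 1)
  }
  out <- cbind(vs, ms[, 1] - ms[, 2], ms[, 1] - ms[, 3], ms[, 2] - ms[, 3])
  colnames(out) <- c("var_1", "var_2", "var_3", "dmean_12", "dmean_13",
                     "dmean_23")
  out
}

#' Observed per-locus summaries of a genotype table
#'
#' Reduces the table to one haplotype per individual (see
#' [oneHaplotypePerIndividual()]) and computes the 6-number summary of every
#' locus, with sample groups taken in annotation order.
#'
#' @param table a [GenotypeTable-class] with exactly 3 samples.
#' @param seed optional seed for the haplotype draw.
#' @return Numeric matrix (loci x 6). Loci where any group has no data are
#'   dropped with a message.
#' @export
observedSummaries <- function(table, seed = NULL) {
  ann <- sampleAnnotation(table)
  if (nrow(ann) != 3) stop("exactly 3 samples required, found ", nrow(ann))
  hap <- oneHaplotypePerIndividual(table, seed = seed)
  pop <- attr(hap, "pop")
  out <- matrix(NA_real_, 0, 6)
  kept <- character(0)
  for (j in seq_len(ncol(hap))) {
    groups <- lapply(ann$label, function(lab) hap[pop == lab, j])
    groups <- lapply(groups, function(v) v[!is.na(v)])
    if (any(vapply(groups, length, integer(1)) < 2)) next
    out <- rbind(out, perLocusSummaries(setNames(groups, ann$label)))
    kept <- c(kept, colnames(hap)[j])
  }
  if (nrow(out) < ncol(hap))
    message(ncol(hap) - nrow(out), " locus/loci dropped for lack of data")
  rownames(out) <- kept
  out
}
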