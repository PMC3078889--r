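# Weir & Cockerham (1984) variance components for codominant diploid data.
# For one locus and r population samples, per allele:
#   a: among-population component (needs r >= 2)
#   b: among-individual-within-population component
#   c: within-individual component
# F_IS ("f") = 1 - sum(c) / sum(b + c);  F_ST ("theta") = sum(a) / sum(a+b+c),
# ratios of sums across alleles and loci (FSTAT convention).

# per-locus components; a1g/a2g are integer allele vectors per individual,
# groups an integer vector in 1..r
wcLocusComponents <- function(x1, x2, groups, r) {
  ok <- !is.na(x1)
  x1 <- x1[ok]; x2 <- x2[ok]; groups <- groups[ok]
  n_i <- tabulate(groups, nbins = r)
  if (any(n_i < 1) || sum(n_i) < 2) return(NULL)
  alleles <- unique(c(x1, x2))
  if (length(alleles) < 2) return(list(a = 0, b = 0, c = 0, poly = FALSE))
  nbar <- mean(n_i)
  nsum <- sum(n_i)
  nc <- if (r > 1) (nsum - sum(n_i^2) / nsum) / (r - 1) else NA_real_
  het <- x1 != x2
  A <- B <- C <- 0
  for (al in alleles) {
    cnt1 <- (x1 == al) + (x2 == al)
    p_i <- vapply(seq_len(r), function(g) {
      gi <- groups == g
      sum(cnt1[gi]) / (2 * n_i[g])
    }, numeric(1))
    h_i <- vapply(seq_len(r), function(g) {
      gi <- groups == g
      sum(het[gi] & cnt1[gi] == 1L) / n_i[g]
    }, numeric(1))
    pbar <- sum(n_i * p_i) / nsum
    hbar <- sum(n_i * h_i) / nsum
    s2 <- if (r > 1) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
    if (r > 1) {
      a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
      A <- A + a
    }
    b <- (nbar / (nbar - 1)) * (inner - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    B <- B + b
    C <- C + hbar / 2
  }
  list(a = A, b = B, c = C, poly = TRUE)
}

#' Weir-Cockerham inbreeding coefficient F_IS
#'
#' Per-locus and multilocus Weir & Cockerham (1984) `f`, combining loci by
#' summing variance components (ratio of sums, not mean of ratios). Loci
#' monomorphic in the sample have an undefined per-locus value and contribute
#' nothing to the multilocus sum.
#'
#' @param table a [GenotypeTable-class].
#' @param sample a sample label.
#' @return List with `perLocus` (named numeric, `NA` where undefined) and
#'   `multilocus`.
#' @export
fIS <- function(table, sample) {
  stopifnot(is(table, "GenotypeTable"))
  keep <- table@pop == sample
  if (sum(keep) < 2) stop("sample ", sample, " has fewer than 2 individuals")
  a1 <- table@a1[keep, , drop = FALSE]
  a2 <- table@a2[keep, , drop = FALSE]
  per <- rep(NA_real_, length(table@loci))
  names(per) <- table@loci
  sb <- sc <- 0
  for (j in seq_along(table@loci)) {
    comp <- wcLocusComponents(a1[, j], a2[, j], rep(1L, nrow(a1)), 1L)
    if (is.null(comp) || !comp$poly) next
    if (comp$b + comp$c > 0) per[j] <- 1 - comp$c / (comp$b + comp$c)
    sb <- sb + comp$b; sc <- sc + comp$c
  }
  multi <- if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_
  list(perLocus = per, multilocus = multi)
}

#' Weir-Cockerham F_ST between two samples with a permutation test
#'
#' Weir & Cockerham (1984) theta across the two samples, combined over loci
#' and alleles as a ratio of summed variance components. The p-value is the
#' fraction of permutations (individuals shuffled between the two samples,
#' sizes preserved) with theta at least as large as observed, with
#' `+1/(nPerm+1)` smoothing.
#'
#' @param table a [GenotypeTable-class] containing both samples.
#' @param sampleA,sampleB sample labels.
#' @param nPerm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return List with `theta` and `p`.
#' @export
fST <- function(table, sampleA, sampleB, nPerm = 1000, seed = NULL) {
  stopifnot(is(table, "GenotypeTable"))
  if (nPerm < 1) stop("nPerm must be >= 1")
  keep <- table@pop %in% c(sampleA, sampleB)
  a1 <- table@a1[keep, , drop = FALSE]
  a2 <- table@a2[keep, , drop = FALSE]
  grp <- ifelse(table@pop[keep] == sampleA, 1L, 2L)
  if (sum(grp == 1) < 2 || sum(grp == 2) < 2)
    stop("each sample needs at least 2 individuals")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  theta <- thetaFromMatrices(a1, a2, grp)
  n <- length(grp)
  hits <- 0L
  for (p in seq_len(nPerm)) {
    gp <- grp[sample.int(n)]
    tp <- thetaFromMatrices(a1, a2, gp)
    if (!is.na(tp) && tp >= theta) hits <- hits + 1L
  }
  list(theta = theta, p = (hits + 1) / (nPerm + 1))
}

thetaFromMatrices <- function(a1, a2, grp) {
  sa <- sabc <- 0
  for (j in seq_len(ncol(a1))) {
    comp <- wcLocusComponents(a1[, j], a2[, j], grp, 2L)
    if (is.null(comp) || !comp$poly) next
    sa <- sa + comp$a
    sabc <- sabc + comp$a + comp$b + comp$c
  }
  if (sabc == 0) return(NA_real_)
  sa / sabc
}
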