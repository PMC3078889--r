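#' @import methods
#' @importFrom stats dnorm pnorm qnorm runif rbinom rmultinom rpois setNames
#'   density integrate ks.test optimize pchisq qchisq var sd quantile ecdf
#' @importFrom utils head tail
#' @useDynLib driftABC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Temporally annotated diploid microsatellite genotypes
#'
#' The central data container: diploid allele calls (repeat counts) for a set
#' of individuals at a set of unlinked microsatellite loci, each individual
#' carrying a population-sample label, and each sample label annotated with a
#' deme and a sampling time in generations before present.
#'
#' Allele calls are stored as two integer matrices (individuals x loci) holding
#' the unordered allele pair in canonical order (`a1 <= a2`). A missing
#' genotype is atomic: both entries are `NA` together; half-called genotypes
#' are invalid. Allele values are strictly positive integers interpreted as
#' repeat counts (use [repeatsToFragmentLength()] if fragment sizes are
#' needed; the conversion is never applied implicitly).
#'
#' @slot loci character vector of locus names.
#' @slot ids character vector of individual identifiers.
#' @slot pop character vector, one sample label per individual.
#' @slot a1,a2 integer matrices (individuals x loci) with the allele pair.
#' @slot annotation data.frame with columns `label`, `deme`
#'   (`"crossriver"` or `"western"`), `time_bp` (generations before present);
#'   one row per sample label, in file/POP-block order.
#'
#' @seealso [GenotypeTable()], [readGenepop()], [alleleFrequencies()]
#' @export
setClass("GenotypeTable",
  representation(loci = "character", ids = "character", pop = "character",
                 a1 = "matrix", a2 = "matrix", annotation = "data.frame"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- length(object@ids); L <- length(object@loci)
  if (!identical(dim(object@a1), c(n, L)) || !identical(dim(object@a2), c(n, L)))
    msg <- c(msg, "allele matrices must be individuals x loci")
  if (length(object@pop) != n)
    msg <- c(msg, "one sample label per individual required")
  if (!identical(is.na(object@a1), is.na(object@a2)))
    msg <- c(msg, "missing genotypes must be atomic (both alleles NA together)")
  ok <- !is.na(object@a1)
  if (any(object@a1[ok] < 1) || any(object@a2[!is.na(object@a2)] < 1))
    msg <- c(msg, "allele repeat counts must be strictly positive integers")
  if (any(object@a1[ok] > object@a2[ok]))
    msg <- c(msg, "allele pairs must be stored in canonical order (a1 <= a2)")
  ann <- object@annotation
  need <- c("label", "deme", "time_bp")
  if (!all(need %in% names(ann)))
    msg <- c(msg, "annotation must have columns label, deme, time_bp")
  else {
    if (anyDuplicated(ann$label)) msg <- c(msg, "sample labels must be unique")
    if (!all(object@pop %in% ann$label))
      msg <- c(msg, "every individual's sample label must appear in the annotation")
    if (!all(ann$deme %in% c("crossriver", "western")))
      msg <- c(msg, "deme must be 'crossriver' or 'western'")
    if (any(ann$time_bp < 0)) msg <- c(msg, "time_bp must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele repeat counts;
#'   the pair is reordered canonically, so the order of the two arguments per
#'   genotype does not matter. `NA` in either allele marks the whole genotype
#'   missing.
#' @param loci locus names (default taken from `colnames(a1)`).
#' @param ids individual identifiers (default from `rownames(a1)`).
#' @param pop character vector of sample labels, one per individual.
#' @param annotation data.frame with columns `label`, `deme`, `time_bp`.
#' @return A [GenotypeTable-class] object.
#' @examples
#' ann <- data.frame(label = "s", deme = "crossriver", time_bp = 0)
#' gt <- GenotypeTable(matrix(c(12L, 10L), 1), matrix(c(14L, 10L), 1),
#'                     loci = c("L1", "L2"), ids = "ind1", pop = "s",
#'                     annotation = ann)
#' @export
GenotypeTable <- function(a1, a2, loci = colnames(a1), ids = rownames(a1),
                          pop, annotation) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(a1)))
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dim(lo) <- dim(hi) <- dim(a1)  # pmin drops dims on zero-row input
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  annotation$label <- as.character(annotation$label)
  annotation$deme <- as.character(annotation$deme)
  annotation$time_bp <- as.integer(annotation$time_bp)
  new("GenotypeTable", loci = as.character(loci), ids = as.character(ids),
      pop = as.character(pop), a1 = lo, a2 = hi,
      annotation = annotation)
}

#' Effective-population-size estimate
#'
#' Point estimate with 95% bounds from a temporal-method estimator. Sizes are
#' diploid individuals; the point and the upper bound may be `Inf` when the
#' observed allele-frequency change is fully explained by sampling.
#'
#' @slot point,lower,upper numeric scalars (may be `Inf`).
#' @slot method character label of the estimator.
#' @slot plan integer, Nei-Tajima sampling plan (1 or 2).
#' @slot details list of method-specific extras (e.g. the multilocus F value,
#'   degrees of freedom, or a likelihood profile).
#' @export
setClass("NeEstimate",
  representation(point = "numeric", lower = "numeric", upper = "numeric",
                 method = "character", plan = "integer", details = "list"))

setValidity("NeEstimate", function(object) {
  p <- object@point
  if (length(p) != 1) return("point must be scalar")
  if (!is.infinite(p) && p <= 0) return("point must be positive or +Inf")
  if (is.finite(object@lower) && is.finite(p) && object@lower > p + 1e-9)
    return("lower bound must not exceed the point estimate")
  if (is.finite(object@upper) && is.finite(p) && object@upper < p - 1e-9)
    return("upper bound must not be below the point estimate")
  TRUE
})

NeEstimate <- function(point, lower, upper, method, plan, details = list()) {
  new("NeEstimate", point = point, lower = lower, upper = upper,
      method = method, plan = as.integer(plan), details = details)
}

#' Reference table for ABC
#'
#' Parameter draws from the prior paired with the per-locus summary vector of
#' one simulated locus each (the independent-loci scheme simulates a single
#' locus per parameter draw).
#'
#' @slot model `"im"` or `"admixture"`.
#' @slot params data.frame of parameter draws on the natural scale.
#' @slot theta numeric matrix of the same draws on the estimation scale
#'   (log10 for loguniform-prior parameters).
#' @slot summaries numeric matrix (draws x 6) of per-locus summary statistics.
#' @slot scheme the sampling scheme data.frame the loci were simulated under.
#' @export
setClass("ReferenceTable",
  representation(model = "character", params = "data.frame",
                 theta = "matrix", summaries = "matrix", scheme = "data.frame"))

setValidity("ReferenceTable", function(object) {
  if (nrow(object@params) != nrow(object@summaries) ||
      nrow(object@params) != nrow(object@theta))
    return("params, theta and summaries must have one row per simulation")
  if (anyNA(object@summaries)) return("summaries must not contain missing values")
  TRUE
})

#' Posterior result from ABC-GLM
#'
#' Weighted posterior sample plus per-parameter kernel-density summaries:
#' mode and nested highest-density intervals. Parameters with loguniform
#' priors are estimated on the log10 scale and back-transformed for
#' reporting, so `mode` and `hdi` are on the natural scale while `theta`,
#' `grid` and `density` are on the estimation scale.
#'
#' @slot parameters parameter names.
#' @slot theta matrix of posterior draws (estimation scale).
#' @slot weights importance weights (sum to 1).
#' @slot mode named numeric, posterior modes on the natural scale.
#' @slot hdi named list; per level (e.g. `"0.9"`) a parameters x 2 matrix of
#'   interval bounds on the natural scale.
#' @slot grid,density lists of per-parameter density grids (estimation scale).
#' @slot log10scale logical vector: which parameters are log10-transformed.
#' @slot support parameters x 2 matrix of prior support (estimation scale).
#' @export
setClass("PosteriorResult",
  representation(parameters = "character", theta = "matrix",
                 weights = "numeric", mode = "numeric", hdi = "list",
                 grid = "list", density = "list", log10scale = "logical",
                 support = "matrix"))

setValidity("PosteriorResult", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  for (lv in names(object@hdi)) {
    h <- object@hdi[[lv]]
    if (any(h[, 1] > h[, 2])) return("HDI bounds out of order")
  }
  TRUE
})

#' Model comparison by Bayes factor
#'
#' @slot log10bf numeric scalar: log10 Bayes factor of the first model over
#'   the second, at the largest retained count requested.
#' @slot curve data.frame with columns `retained` and `log10bf`: the
#'   robustness of the Bayes factor to the number of retained simulations.
#' @slot models character vector of the two model labels, in order.
#' @export
setClass("ModelComparisonResult",
  representation(log10bf = "numeric", curve = "data.frame", models = "character"))

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@ids), "individuals x",
      length(object@loci), "loci\n")
  ann <- object@annotation
  for (i in seq_len(nrow(ann))) {
    n_i <- sum(object@pop == ann$label[i])
    cat(sprintf("  %s (%s, %d gen BP): %d individuals\n",
                ann$label[i], ann$deme[i], ann$time_bp[i], n_i))
  }
  miss <- mean(is.na(object@a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

setMethod("show", "NeEstimate", function(object) {
  fmt <- function(x) if (is.infinite(x)) "Inf" else sprintf("%.1f", x)
  cat(sprintf("NeEstimate (%s, plan %d): Ne = %s [95%%: %s, %s]\n",
              object@method, object@plan, fmt(object@point),
              fmt(object@lower), fmt(object@upper)))
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable (%s model): %d simulations, %d parameters, %d summaries\n",
              object@model, nrow(object@params), ncol(object@theta),
              ncol(object@summaries)))
})

setMethod("show", "PosteriorResult", function(object) {
  cat("PosteriorResult:", length(object@parameters), "parameters\n")
  lv <- names(object@hdi)
  for (i in seq_along(object@parameters)) {
    p <- object@parameters[i]
    h <- object@hdi[[length(lv)]][p, ]
    cat(sprintf("  %-18s mode %.4g  HDI%s [%.4g, %.4g]\n",
                p, object@mode[p], lv[length(lv)], h[1], h[2]))
  }
})

setMethod("show", "ModelComparisonResult", function(object) {
  cat(sprintf("ModelComparisonResult: log10 BF (%s over %s) = %.2f\n",
              object@models[1], object@models[2], object@log10bf))
  cat("  robustness:", paste(sprintf("%d:%.2f", object@curve$retained,
                                     object@curve$log10bf), collapse = "  "), "\n")
})
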