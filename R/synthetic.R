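#' Default study-shaped design
#'
#' The sample layout the synthetic generator emulates: a historical sample of
#' 14 individuals of the focal population taken 5 generations before
#' present, 71 modern focal individuals and 92 modern outgroup individuals,
#' at 8 unlinked microsatellite loci.
#'
#' @return data.frame with columns `label`, `deme`, `time_bp`,
#'   `n_individuals`.
#' @export
studyDesign <- function() {
  data.frame(label = c("crossriver_historical", "crossriver_modern",
                       "western_modern"),
             deme = c("crossriver", "crossriver", "western"),
             time_bp = c(5L, 0L, 0L),
             n_individuals = c(14L, 71L, 92L))
}

#' Generate a study-shaped diploid dataset
#'
#' Simulates `2 n` haploid gene copies per sample group under the serial
#' coalescent ([simulateLocus()]) and pairs consecutive haplotypes into
#' diploid genotypes (random mating within the panmictic demes makes the
#' pairing exchangeable), then applies uniform per-genotype missingness.
#'
#' @param params demographic parameters ([IMModelParams-class],
#'   [AdmixtureModelParams-class], named list or one-row data.frame).
#' @param design a design data.frame (see [studyDesign()]).
#' @param kLoci number of loci.
#' @param missingRate per-genotype missing probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @param outPrefix if non-`NULL`, also write `<outPrefix>.gen` (Genepop,
#'   3-digit dialect) and `<outPrefix>_samples.txt` (annotation sidecar).
#' @return A [GenotypeTable-class].
#' @export
generateStudyLikeDataset <- function(params, design = studyDesign(),
                                     kLoci = 8, missingRate = 0, seed = NULL,
                                     outPrefix = NULL) {
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  scheme <- samplingScheme(design$deme, 2L * design$n_individuals,
                           design$time_bp, label = design$label)
  loci <- simulateDataset(params, scheme, kLoci = kLoci)
  nInd <- sum(design$n_individuals)
  a1 <- a2 <- matrix(NA_integer_, nInd, kLoci)
  for (k in seq_len(kLoci)) {
    hap <- unlist(loci[[k]], use.names = FALSE)
    odd <- seq(1, length(hap), by = 2)
    a1[, k] <- pmax(hap[odd], 1L)
    a2[, k] <- pmax(hap[odd + 1L], 1L)
  }
  if (missingRate > 0) {
    miss <- matrix(runif(nInd * kLoci) < missingRate, nInd, kLoci)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  pop <- rep(design$label, design$n_individuals)
  ids <- unlist(lapply(seq_len(nrow(design)), function(g)
    sprintf("%s_%03d", design$label[g], seq_len(design$n_individuals[g]))))
  gt <- GenotypeTable(a1, a2, loci = sprintf("locus%02d", seq_len(kLoci)),
                      ids = ids, pop = pop,
                      annotation = design[c("label", "deme", "time_bp")])
  if (!is.null(outPrefix))
    writeGenepop(gt, paste0(outPrefix, ".gen"),
                 annotationPath = paste0(outPrefix, "_samples.txt"))
  gt
}

#' Generate temporal Wright-Fisher calibration data
#'
#' Forward multinomial Wright-Fisher drift: per locus, initial allele
#' frequencies are drawn flat-Dirichlet over `nAlleles` alleles, the
#' population of `2 ne` gene copies drifts for `t` generations, and `s0`
#' and `st` gene copies are sampled multinomially at the two endpoints
#' (non-destructive sampling, i.e. the sampling-plan-2 situation).
#'
#' @param ne diploid effective size (>= 2).
#' @param s0,st gene copies sampled at time 0 and time t.
#' @param t generations of drift.
#' @param kLoci number of independent loci.
#' @param nAlleles alleles per locus.
#' @param seed optional integer seed.
#' @return List of temporal pairs (see [temporalPair()]) with attribute `t`.
#' @export
generateTemporalWFDataset <- function(ne, s0, st, t, kLoci = 8, nAlleles = 10,
                                      seed = NULL) {
  if (ne < 2) stop("ne must be >= 2")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  twoN <- 2 * ne
  pairs <- list()
  for (k in seq_len(kLoci)) {
    p0 <- rexp(nAlleles)
    p0 <- p0 / sum(p0)
    x <- drop(rmultinom(1, s0, p0))
    p <- p0
    for (g in seq_len(t)) p <- drop(rmultinom(1, twoN, p)) / twoN
    y <- drop(rmultinom(1, st, p))
    names(x) <- names(y) <- paste0("a", seq_len(nAlleles))
    pairs[[paste0("locus", k)]] <- temporalPair(x / s0, y / st, s0, st)
  }
  attr(pairs, "t") <- as.integer(t)
  pairs
}
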