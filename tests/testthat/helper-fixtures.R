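# in-code fixtures shared across test files

# a GenotypeTable from explicit allele matrices
makeTable <- function(a1, a2, pop, loci = NULL, deme = NULL, time_bp = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  labs <- unique(pop)
  if (is.null(deme)) deme <- rep("crossriver", length(labs))
  if (is.null(time_bp)) time_bp <- rep(0L, length(labs))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  GenotypeTable(a1, a2, loci = loci, ids = sprintf("i%d", seq_len(nrow(a1))),
                pop = pop,
                annotation = data.frame(label = labs, deme = deme,
                                        time_bp = time_bp))
}

# a random valid diploid table for round-trip properties
randomTable <- function(nInd = 12, nLoci = 4, nPop = 2, missingRate = 0.1) {
  labs <- paste0("pop", seq_len(nPop))
  pop <- sort(rep_len(labs, nInd))
  a1 <- matrix(sample(5:30, nInd * nLoci, replace = TRUE), nInd)
  a2 <- matrix(sample(5:30, nInd * nLoci, replace = TRUE), nInd)
  miss <- matrix(runif(nInd * nLoci) < missingRate, nInd)
  a1[miss] <- NA; a2[miss] <- NA
  makeTable(a1, a2, pop,
            deme = rep_len(c("crossriver", "western"), nPop),
            time_bp = rep_len(c(0L, 5L), nPop))
}

# single panmictic constant-size deme: everything collapses to the
# ancestral population at time 0
singleDemeParams <- function(N, mu) {
  IMModelParams(two_Nm = 0, ratio_old_now = 1, n_cr_now = N, n_ancestral = N,
                n_western = N, t_divergence = 0, t_bottleneck = 0,
                t_migration = 0, mu = mu)
}

writeTempGenepop <- function(lines) {
  f <- tempfile(fileext = ".gen")
  writeLines(lines, f)
  f
}
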