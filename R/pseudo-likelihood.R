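#' Pseudo-likelihood temporal estimate of Ne
#'
#' Likelihood-based temporal estimator that reduces every multiallelic locus
#' to a biallelic state by taking each allele in turn as the focal allele and
#' pooling all others. For one focal allele with sample counts `b0` (out of
#' `n0` gene copies at time 0) and `bt` (out of `nt` at time t), the
#' likelihood of `Ne` is the probability of the time-t count given the time-0
#' count, integrating binomial sampling at both ends over Wright-Fisher drift
#' across `t` generations with a uniform prior on the latent initial
#' frequency:
#' `P(bt | b0; Ne) = sum_i pi_i Bin(b0; n0, i/2Ne) [W^t]_i. Bin(bt; nt, ./2Ne)
#'  / sum_i pi_i Bin(b0; n0, i/2Ne)`.
#' Within a locus, focal-allele log-likelihoods are averaged (not summed) to
#' avoid pseudo-replication; locus log-likelihoods are summed. The point
#' estimate is the grid argmax and the 95% bounds come from the profile at a
#' drop of 1.92 log-units (with log-linear interpolation between grid
#' points); the upper bound is `Inf` when the profile at the top of the grid
#' stays within 1.92 of the maximum.
#'
#' The Wright-Fisher transition is exact (binomial transition matrix on the
#' `2Ne + 1` copy-number states) for `2Ne <= 500` and switches to a
#' discretized truncated-normal diffusion approximation above; the switch is
#' continuous enough to keep the profile smooth (cross-checked at the
#' boundary in the test suite).
#'
#' @param pairs list of temporal pairs ([temporalPair()]).
#' @param t generations elapsed (default: the `t` attribute of `pairs`).
#' @param neGridMax top of the Ne grid (diploid individuals); the profile is
#'   evaluated on a log-spaced grid from `neGridMin` to `neGridMax`.
#' @param neGridMin bottom of the grid.
#' @param gridLength number of grid points.
#' @return An [NeEstimate-class]; `details$profile` holds the grid and the
#'   profile log-likelihood.
#' @export
pseudoLikelihoodNe <- function(pairs, t = attr(pairs, "t"), neGridMax = 3000,
                               neGridMin = 5, gridLength = 40) {
  if (neGridMax < 10) stop("neGridMax must be >= 10")
  pairs <- asPairList(pairs)
  poly <- vapply(pairs, function(p) length(p$x) >= 2, logical(1))
  if (!any(poly)) {
    warning("all loci monomorphic: pseudo-likelihood is flat, returning Inf")
    return(NeEstimate(Inf, NA_real_, NA_real_, method = "pseudo-likelihood",
                      plan = 1L, details = list(profile = NULL)))
  }
  pairs <- pairs[poly]
  neGrid <- exp(seq(log(neGridMin), log(neGridMax), length.out = gridLength))
  # continuity splice between the exact chain (2Ne <= exactMax) and the
  # diffusion approximation: the diffusion branch is offset so the two
  # methods agree at the switch point, keeping the profile smooth
  exactMax <- 500
  neB <- exactMax / 2
  delta <- 0
  if (any(2 * neGrid > exactMax) && any(2 * neGrid <= exactMax))
    delta <- pseudoLogLik(pairs, neB, t, exactMax = exactMax) -
      pseudoLogLik(pairs, neB, t, exactMax = 0)
  ll <- vapply(neGrid, function(ne) {
    if (2 * ne <= exactMax) pseudoLogLik(pairs, ne, t, exactMax = exactMax)
    else pseudoLogLik(pairs, ne, t, exactMax = 0) + delta
  }, numeric(1))
  iMax <- which.max(ll)
  point <- neGrid[iMax]
  thr <- ll[iMax] - qchisq(0.95, 1) / 2
  logNe <- log(neGrid)
  crossing <- function(side) {
    if (side == "lower") {
      idx <- seq_len(iMax)
      below <- which(ll[idx] < thr)
      if (!length(below)) return(neGrid[1])
      i <- max(below)  # interpolate between i and i+1
      exp(logNe[i] + (thr - ll[i]) / (ll[i + 1] - ll[i]) * (logNe[i + 1] - logNe[i]))
    } else {
      idx <- iMax:length(ll)
      below <- which(ll[idx] < thr)
      if (!length(below)) return(Inf)
      i <- iMax + min(below) - 1L
      exp(logNe[i - 1] + (thr - ll[i - 1]) / (ll[i] - ll[i - 1]) *
            (logNe[i] - logNe[i - 1]))
    }
  }
  NeEstimate(point, crossing("lower"), crossing("upper"),
             method = "pseudo-likelihood", plan = 1L,
             details = list(profile = data.frame(ne = neGrid, logLik = ll),
                            t = t))
}

# profile log-likelihood at one Ne: sum over loci of the mean over focal
# alleles of log P(bt | b0)
pseudoLogLik <- function(pairs, ne, t, exactMax = 500) {
  twoN <- round(2 * ne)
  b0 <- bt <- n0 <- nt <- locus <- integer(0)
  for (li in seq_along(pairs)) {
    p <- pairs[[li]]
    k <- length(p$x)
    b0 <- c(b0, as.integer(round(p$x * p$n0)))
    bt <- c(bt, as.integer(round(p$y * p$nt)))
    n0 <- c(n0, rep(p$n0, k)); nt <- c(nt, rep(p$nt, k))
    locus <- c(locus, rep(li, k))
  }
  lik <- if (twoN <= exactMax) {
    pseudoLikExact(twoN, t, b0, bt, n0, nt)
  } else {
    pseudoLikDiffusion(ne, t, b0, bt, n0, nt)
  }
  perFocal <- log(pmax(lik, 1e-300))
  sum(tapply(perFocal, locus, mean))
}

# exact Wright-Fisher copy-number chain
pseudoLikExact <- function(twoN, t, b0, bt, n0, nt) {
  states <- 0:twoN
  p <- states / twoN
  W <- outer(states, p, function(j, pp) dbinom(j, twoN, pp))  # W[j+1, i+1]
  A <- t(vapply(seq_along(b0), function(f) dbinom(b0[f], n0[f], p), numeric(twoN + 1)))
  norm <- rowSums(A)
  for (g in seq_len(t)) A <- A %*% t(W)
  B <- t(vapply(seq_along(bt), function(f) dbinom(bt[f], nt[f], p), numeric(twoN + 1)))
  rowSums(A * B) / norm
}

# discretized normal diffusion approximation of the drift kernel; cell
# probabilities are integrated between cell edges, with the two end cells
# absorbing the tail mass (fixation/loss)
pseudoLikDiffusion <- function(ne, t, b0, bt, n0, nt, nGrid = 256) {
  p <- (seq_len(nGrid) - 0.5) / nGrid
  edges <- c(-Inf, seq_len(nGrid - 1) / nGrid, Inf)
  shrink <- 1 - (1 - 1 / (2 * ne))^t
  K <- vapply(p, function(p0) {
    s <- sqrt(p0 * (1 - p0) * shrink)
    diff(pnorm(edges, p0, s))
  }, numeric(nGrid))  # K[ , i] = kernel from p0 = p[i]
  A <- t(vapply(seq_along(b0), function(f) dbinom(b0[f], n0[f], p), numeric(nGrid)))
  norm <- rowSums(A)
  A <- A %*% t(K)
  B <- t(vapply(seq_along(bt), function(f) dbinom(bt[f], nt[f], p), numeric(nGrid)))
  rowSums(A * B) / norm
}
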