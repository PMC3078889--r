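#' Build an ABC reference table of single-locus simulations
#'
#' Draws `nSims` parameter vectors from the prior and simulates
#' `kLociPerSim` loci per draw (default 1: the independent-loci scheme
#' simulates a single locus per parameter vector, which cuts the simulation
#' cost to a fraction 1/K of simulating every observed locus). Each row
#' pairs the draw with the per-locus summary vector (averaged across loci
#' when `kLociPerSim > 1`).
#'
#' @param model `"im"` or `"admixture"`.
#' @param nSims number of simulations (>= 100).
#' @param scheme sampling scheme (see [samplingScheme()]).
#' @param kLociPerSim loci per parameter draw.
#' @param seed optional integer seed.
#' @param verbose log progress every 10,000 simulations.
#' @return A [ReferenceTable-class].
#' @export
buildReferenceTable <- function(model = c("im", "admixture"), nSims = 1e5,
                                scheme = defaultSamplingScheme(),
                                kLociPerSim = 1, seed = NULL, verbose = FALSE) {
  model <- match.arg(model)
  if (nSims < 100) stop("nSims must be >= 100")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  params <- samplePrior(nSims, model)
  nTot <- sum(scheme$n)
  demeCode <- rep(ifelse(scheme$deme == "crossriver", 0L, 1L), scheme$n)
  sampTime <- rep(scheme$time, scheme$n)
  modelCode <- if (model == "im") 0L else 1L
  S <- matrix(0, nSims, 6)
  X <- matrix(0L, kLociPerSim, nTot)
  for (i in seq_len(nSims)) {
    p <- params[i, ]
    tAdm <- if (model == "im") 0 else p$t_admixture_frac * p$t_divergence
    gam <- if (model == "im") 0 else p$gamma_admixture
    twoNm <- if (model == "im") p$two_Nm else 0
    tMig <- if (model == "im") p$t_migration else 0
    for (k in seq_len(kLociPerSim))
      X[k, ] <- .simulateLocusCpp(demeCode, sampTime, p$n_cr_now,
                                  p$ratio_old_now, p$n_ancestral, p$n_western,
                                  p$t_divergence, p$t_bottleneck, twoNm, tMig,
                                  tAdm, gam, modelCode, p$mu, 100L)$alleles
    sm <- summariesFromMatrix(X, scheme$n)
    S[i, ] <- colMeans(sm)
    if (verbose && i %% 10000 == 0)
      message("  simulated ", i, " / ", nSims)
  }
  colnames(S) <- colnames(summariesFromMatrix(X, scheme$n))
  new("ReferenceTable", model = model, params = params,
      theta = transformParams(params, model), summaries = S, scheme = scheme)
}

# Gaussianizing transform applied to summaries before the linear model:
# within-group repeat-length variances are strongly right-skewed (their
# scale is a product of sizes and mutation rate), so they enter the GLM as
# log(1 + var); mean differences are symmetric already and stay linear.
glmSummaryTransform <- function(S) {
  vc <- grep("^var_", colnames(S))
  if (!length(vc)) vc <- 1:3
  # sign-symmetric log1p: identical to log1p on true (non-negative)
  # variances, but finite for arbitrary numeric input
  S[, vc] <- sign(S[, vc]) * log1p(abs(S[, vc]))
  S
}

# standardize summaries; returns list(S, obs, center, scale)
standardizeSummaries <- function(S, obs, center = colMeans(S),
                                 scale = apply(S, 2, sd)) {
  scale[scale == 0] <- 1
  list(S = sweep(sweep(S, 2, center), 2, scale, "/"),
       obs = sweep(sweep(obs, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# pooled Euclidean rejection distance: mean over observed loci of the
# distance between a reference row and each locus' summary vector
rejectionDistance <- function(Sstd, obsStd) {
  d <- 0
  for (k in seq_len(nrow(obsStd)))
    d <- d + sqrt(rowSums(sweep(Sstd, 2, obsStd[k, ])^2))
  d / nrow(obsStd)
}

# regression basis for the Gaussian linear model: the estimation-scale
# parameters plus two physically motivated terms that linearize the
# dominant summary responses -- the log mutation rate (variances scale with
# mu) and the log expected coalescence depth log10(t_div + 2 N_ancestral),
# which is convex in log10(N_ancestral) and would otherwise bias the
# ancestral-size direction of a straight-line fit.
glmFeatures <- function(theta) {
  mu <- pmax(theta[, "mu"], 1e-12)
  depth <- log10(10^theta[, "t_divergence"] + 2 * 10^theta[, "n_ancestral"])
  cbind(theta, lmu = log10(mu), ldepth = depth, lmudepth = log10(mu) + depth)
}

# multivariate Gaussian linear model of summaries on parameter features,
# fitted on the retained rows: s = c + B' phi(theta) + e,  e ~ N(0, Sigma).
# Structurally collinear summary columns (the three pairwise mean
# differences have rank 2) are dropped from the Gaussian model via a rank
# check, so Sigma is the covariance of a full-rank summary subset; a ridge
# with a warning remains as the fallback for accidental singularity.
fitSummaryGlm <- function(theta, S, ridge = 1e-8) {
  qrS <- qr(scale(S, scale = FALSE), tol = 1e-7)
  use <- sort(qrS$pivot[seq_len(qrS$rank)])
  S <- S[, use, drop = FALSE]
  X <- cbind(1, glmFeatures(theta))
  qrX <- qr(X)
  coef <- qr.coef(qrX, S)
  coef[is.na(coef)] <- 0
  resid <- S - X %*% coef
  Sigma <- crossprod(resid) / max(nrow(S) - ncol(X), 1)
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) {
    warning("singular summary covariance: ridge-regularized")
    Sigma <- Sigma + diag(ridge * max(mean(diag(Sigma)), 1e-12), ncol(Sigma))
    U <- chol(Sigma)
  }
  list(c = coef[1, ], B = coef[-1, , drop = FALSE], Sigma = Sigma, U = U,
       SigmaInv = chol2inv(U), logDet = 2 * sum(log(diag(U))), use = use)
}

# weighted refit of the Gaussian linear model, localized in parameter space:
# rows are weighted by a Gaussian centered on the pilot posterior, so the
# linear approximation (and the residual covariance, which is strongly
# parameter-dependent) is fitted where the posterior actually lives instead
# of across the whole prior range. Falls back to the global fit when too few
# rows carry weight.
refitSummaryGlmLocal <- function(theta, S, mHat, Uc, fallback) {
  lwRows <- dmvnormLog(theta, mHat, Uc)
  w <- exp(lwRows - max(lwRows))
  keep <- w > 1e-10
  if (sum(keep) < 20 * (ncol(theta) + 4)) return(fallback)
  theta <- theta[keep, , drop = FALSE]
  S <- S[keep, , drop = FALSE]
  sw <- sqrt(w[keep] / mean(w[keep]))
  qrS <- qr(scale(S, scale = FALSE), tol = 1e-7)
  use <- sort(qrS$pivot[seq_len(qrS$rank)])
  X <- cbind(1, glmFeatures(theta)) * sw
  Sw <- S[, use, drop = FALSE] * sw
  qrX <- qr(X)
  coef <- qr.coef(qrX, Sw)
  coef[is.na(coef)] <- 0
  resid <- Sw - X %*% coef
  Sigma <- crossprod(resid) / max(nrow(Sw) - ncol(X), 1)
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(fallback)
  list(c = coef[1, ], B = coef[-1, , drop = FALSE], Sigma = Sigma, U = U,
       SigmaInv = chol2inv(U), logDet = 2 * sum(log(diag(U))), use = use)
}

# log of prod_k N(obs_k; c + B' theta, Sigma) for each row of thetaMat;
# includes the full normalizing constant (needed for marginal likelihoods)
glmLogLik <- function(fit, thetaMat, obsStd) {
  obsStd <- obsStd[, fit$use, drop = FALSE]
  K <- nrow(obsStd)
  Mu <- glmFeatures(thetaMat) %*% fit$B
  q <- 0
  for (k in seq_len(K)) {
    Rk <- sweep(-Mu, 2, obsStd[k, ] - fit$c, "+")  # obs_k - c - B'theta
    q <- q + rowSums((Rk %*% fit$SigmaInv) * Rk)
  }
  -0.5 * q - K * 0.5 * (fit$logDet + ncol(obsStd) * log(2 * pi))
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' ABC posterior with general-linear-model adjustment for independent loci
#'
#' Rejection step plus Gaussian linear post-adjustment: the reference-table
#' summaries are standardized, the closest `retainFraction` of rows by
#' Euclidean distance (pooled over the K observed loci) is retained, and a
#' linear Gaussian model `s = c + B' theta + e`, `e ~ N(0, Sigma)` is fitted
#' to the retained rows. The posterior density is proportional to
#' `prior(theta) * prod_k N(s_obs_k; c + B' theta, Sigma)` across the K
#' independently observed loci -- the product structure is what lets a
#' single-locus reference table serve a multi-locus observation. The
#' posterior is sampled by self-normalized importance sampling from a
#' defensive mixture of the prior and a Gaussian centered on the analytic
#' maximum of the adjusted likelihood; modes and nested 50/90/95% HDIs come
#' from weighted kernel densities per parameter ([posteriorModeHdi()]),
#' computed on the log10 scale for loguniform-prior parameters and
#' back-transformed for reporting.
#'
#' @param refTable a [ReferenceTable-class].
#' @param obsSummaries numeric matrix (K loci x 6) of observed per-locus
#'   summaries ([observedSummaries()] or [perLocusSummaries()] rows).
#' @param retainFraction fraction of reference rows retained in (0, 1].
#' @param nPosterior importance-sample size.
#' @param levels HDI levels.
#' @param seed optional integer seed.
#' @return A [PosteriorResult-class].
#' @export
abcGlmPosterior <- function(refTable, obsSummaries, retainFraction = 0.05,
                            nPosterior = 20000, levels = c(0.5, 0.9, 0.95),
                            seed = NULL) {
  stopifnot(is(refTable, "ReferenceTable"))
  obsSummaries <- rbind(obsSummaries)
  if (nrow(obsSummaries) < 1) stop("at least one observed locus required")
  if (ncol(obsSummaries) != ncol(refTable@summaries))
    stop("summary dimension mismatch")
  if (retainFraction <= 0 || retainFraction > 1)
    stop("retainFraction must be in (0, 1]")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  model <- refTable@model
  std <- standardizeSummaries(glmSummaryTransform(refTable@summaries),
                              glmSummaryTransform(obsSummaries))
  nRet <- max(ceiling(retainFraction * nrow(std$S)), 50)
  dist <- rejectionDistance(std$S, std$obs)
  ret <- order(dist)[seq_len(nRet)]
  fit <- fitSummaryGlm(refTable@theta[ret, , drop = FALSE],
                       std$S[ret, , drop = FALSE])

  d <- ncol(refTable@theta)

  # stage 1: pilot prior sample locates the posterior bulk under the
  # globally fitted model
  n1 <- max(4000, ceiling(nPosterior / 4))
  th1 <- transformParams(samplePrior(n1, model), model)
  lw1 <- glmLogLik(fit, th1, std$obs)
  w1 <- exp(lw1 - logSumExp(lw1))
  mHat <- colSums(th1 * w1)
  Ctr <- sweep(th1, 2, mHat)
  CHat <- crossprod(Ctr * sqrt(w1)) / max(1 - sum(w1^2), 1e-12)
  CHat <- 2 * (CHat + t(CHat)) / 2 + diag(1e-8, d)
  Uv <- tryCatch(chol(CHat), error = function(e) {
    chol(diag(apply(th1, 2, var), d))
  })

  # refit the linear model locally around the pilot posterior
  fit <- refitSummaryGlmLocal(refTable@theta, std$S, mHat, Uv, fallback = fit)

  # stage 2: defensive mixture of prior and pilot-located Gaussian
  nHalf <- ceiling(nPosterior / 2)
  thPrior <- transformParams(samplePrior(nHalf, model), model)
  thGauss <- matrix(rnorm(nHalf * d), nHalf) %*% Uv
  thGauss <- sweep(thGauss, 2, mHat, "+")
  colnames(thGauss) <- colnames(thPrior)
  theta <- rbind(thPrior, thGauss)

  lp <- priorLogDensity(theta, model)
  ll <- glmLogLik(fit, theta, std$obs)
  lg <- dmvnormLog(theta, mHat, Uv)
  lq <- apply(cbind(lp, lg), 1, function(z) logSumExp(z + log(0.5)))
  lw <- lp + ll - lq
  lw[!is.finite(lp)] <- -Inf
  w <- exp(lw - logSumExp(lw))

  support <- priorSupport(model)
  lg10 <- log10Params(model)
  pars <- colnames(theta)
  modes <- setNames(numeric(d), pars)
  grids <- dens <- vector("list", d)
  names(grids) <- names(dens) <- pars
  hdis <- lapply(levels, function(l) {
    m <- matrix(NA_real_, d, 2, dimnames = list(pars, c("lower", "upper")))
    m
  })
  names(hdis) <- as.character(levels)
  for (j in seq_len(d)) {
    r <- posteriorModeHdi(theta[, j], weights = w, levels = levels,
                          support = support[j, ])
    back <- function(x) backTransform(x, pars[j], model)
    modes[j] <- back(r$mode)
    for (lv in names(r$hdi)) hdis[[lv]][j, ] <- back(r$hdi[[lv]])
    grids[[j]] <- r$grid; dens[[j]] <- r$density
  }
  new("PosteriorResult", parameters = pars, theta = theta, weights = w,
      mode = modes, hdi = hdis, grid = grids, density = dens,
      log10scale = unname(lg10), support = support)
}

# log N(x; m, V) with U = chol(V), rows of x
dmvnormLog <- function(x, m, U) {
  z <- forwardsolve(t(U), t(sweep(x, 2, m)))
  -0.5 * colSums(z^2) - sum(log(diag(U))) - 0.5 * ncol(x) * log(2 * pi)
}

#' Posterior quantile of a parameter value
#'
#' Weighted empirical CDF of the posterior sample at a (natural-scale)
#' parameter value; used for pseudo-observed-dataset calibration.
#'
#' @param post a [PosteriorResult-class].
#' @param param parameter name.
#' @param value natural-scale value.
#' @return Numeric in `[0, 1]`.
#' @export
posteriorQuantile <- function(post, param, value) {
  j <- match(param, post@parameters)
  if (is.na(j)) stop("unknown parameter: ", param)
  v <- if (post@log10scale[j]) log10(value) else value
  sum(post@weights[post@theta[, j] <= v])
}

#' Bayes-factor comparison of two demographic models
#'
#' For each model, the marginal density of the observed per-locus summaries
#' under the model's fitted Gaussian linear adjustment, multiplied across
#' loci and integrated over the prior by Monte Carlo:
#' `m = E_prior[ prod_k N(s_obs_k; c + B' theta, Sigma) ]`. Both models'
#' summaries are standardized with pooled statistics so their densities are
#' comparable. The log10 Bayes factor `log10(m_A) - log10(m_B)` is evaluated
#' at every requested retained count, giving the robustness curve; the
#' headline value is taken at the largest count.
#'
#' @param refA,refB [ReferenceTable-class] objects for the two models (built
#'   against the same scheme and summaries).
#' @param obsSummaries observed per-locus summary matrix (K x 6).
#' @param retainedCounts integer vector of retained-simulation counts.
#' @param nMarginal Monte-Carlo sample size for the prior integration.
#' @param seed optional integer seed.
#' @return A [ModelComparisonResult-class]; positive `log10bf` favors the
#'   first model.
#' @export
bayesFactor <- function(refA, refB, obsSummaries,
                        retainedCounts = c(500, 1000, 2500),
                        nMarginal = 20000, seed = NULL) {
  stopifnot(is(refA, "ReferenceTable"), is(refB, "ReferenceTable"))
  obsSummaries <- rbind(obsSummaries)
  if (ncol(obsSummaries) != ncol(refA@summaries) ||
      ncol(refA@summaries) != ncol(refB@summaries))
    stop("summary dimension mismatch between models and observation")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  obsT <- glmSummaryTransform(obsSummaries)
  pooled <- glmSummaryTransform(rbind(refA@summaries, refB@summaries))
  center <- colMeans(pooled); scale <- apply(pooled, 2, sd)
  logM <- function(ref, nRet) {
    std <- standardizeSummaries(glmSummaryTransform(ref@summaries), obsT,
                                center, scale)
    nRet <- min(nRet, nrow(std$S))
    ret <- order(rejectionDistance(std$S, std$obs))[seq_len(nRet)]
    fit <- fitSummaryGlm(ref@theta[ret, , drop = FALSE],
                         std$S[ret, , drop = FALSE])
    th <- transformParams(samplePrior(nMarginal, ref@model), ref@model)
    ll <- glmLogLik(fit, th, std$obs)
    logSumExp(ll) - log(nMarginal)
  }
  curve <- data.frame(retained = sort(retainedCounts), log10bf = NA_real_)
  for (i in seq_len(nrow(curve))) {
    nr <- curve$retained[i]
    curve$log10bf[i] <- (logM(refA, nr) - logM(refB, nr)) / log(10)
  }
  new("ModelComparisonResult",
      log10bf = curve$log10bf[nrow(curve)], curve = curve,
      models = c(refA@model, refB@model))
}
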