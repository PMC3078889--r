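#' Demographic model parameter containers
#'
#' Two demographies for a focal population ("crossriver") and a large
#' outgroup population ("western") that merge into a single ancestral
#' population `t_divergence` generations back:
#'
#' * **Isolation with migration (IM)**: after divergence the two populations
#'   exchange migrants at scaled rate `two_Nm` (2Nm migrant gene copies per
#'   generation, symmetric, each deme's rate scaled by its own size) until
#'   `t_migration` generations before present, with
#'   `t_migration <= t_divergence`. The focal population has constant size
#'   `n_cr_now * ratio_old_now` until `t_bottleneck` generations ago, when an
#'   exponential decline begins that reaches `n_cr_now` at present.
#' * **Secondary admixture**: divergence in strict isolation, but at
#'   `t_admixture_frac * t_divergence` generations ago a fraction
#'   `gamma_admixture` of the focal population is replaced by immigrants
#'   from the outgroup.
#'
#' Sizes are diploid effective sizes; times are generations before present;
#' `mu` is the per-locus per-generation stepwise-mutation rate.
#'
#' @slot two_Nm,ratio_old_now,n_cr_now,n_ancestral,n_western,t_divergence,t_bottleneck,t_migration,mu
#'   numeric scalars (see above).
#' @name demographic-models
NULL

#' @rdname demographic-models
#' @export
setClass("IMModelParams",
  representation(two_Nm = "numeric", ratio_old_now = "numeric",
                 n_cr_now = "numeric", n_ancestral = "numeric",
                 n_western = "numeric", t_divergence = "numeric",
                 t_bottleneck = "numeric", t_migration = "numeric",
                 mu = "numeric"))

#' @rdname demographic-models
#' @slot t_admixture_frac fraction of `t_divergence` at which the admixture
#'   pulse occurs, in (0,1).
#' @slot gamma_admixture replaced fraction of the focal population, in (0,1).
#' @export
setClass("AdmixtureModelParams",
  representation(ratio_old_now = "numeric", n_cr_now = "numeric",
                 n_ancestral = "numeric", n_western = "numeric",
                 t_divergence = "numeric", t_bottleneck = "numeric",
                 t_admixture_frac = "numeric", gamma_admixture = "numeric",
                 mu = "numeric"))

validSizes <- function(object) {
  msg <- character()
  if (object@n_cr_now <= 0 || object@n_ancestral <= 0 || object@n_western <= 0)
    msg <- c(msg, "all effective sizes must be positive")
  if (object@ratio_old_now < 1)
    msg <- c(msg, "ratio_old_now must be >= 1")
  if (object@t_bottleneck > object@t_divergence)
    msg <- c(msg, "t_bottleneck must not exceed t_divergence")
  if (object@t_bottleneck < 0 || object@t_divergence < 0)
    msg <- c(msg, "times must be non-negative")
  if (object@mu < 0) msg <- c(msg, "mu must be non-negative")
  msg
}

setValidity("IMModelParams", function(object) {
  msg <- validSizes(object)
  if (object@two_Nm < 0) msg <- c(msg, "two_Nm must be non-negative")
  if (object@t_migration > object@t_divergence)
    msg <- c(msg, "t_migration must not exceed t_divergence")
  if (length(msg)) msg else TRUE
})

setValidity("AdmixtureModelParams", function(object) {
  msg <- validSizes(object)
  if (object@t_admixture_frac <= 0 || object@t_admixture_frac >= 1)
    msg <- c(msg, "t_admixture_frac must be in (0,1)")
  if (object@gamma_admixture <= 0 || object@gamma_admixture >= 1)
    msg <- c(msg, "gamma_admixture must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @rdname demographic-models
#' @param two_Nm,ratio_old_now,n_cr_now,n_ancestral,n_western numeric.
#' @param t_divergence,t_bottleneck,t_migration,mu numeric.
#' @export
IMModelParams <- function(two_Nm, ratio_old_now, n_cr_now, n_ancestral,
                          n_western, t_divergence, t_bottleneck, t_migration,
                          mu) {
  new("IMModelParams", two_Nm = two_Nm, ratio_old_now = ratio_old_now,
      n_cr_now = n_cr_now, n_ancestral = n_ancestral, n_western = n_western,
      t_divergence = t_divergence, t_bottleneck = t_bottleneck,
      t_migration = t_migration, mu = mu)
}

#' @rdname demographic-models
#' @param t_admixture_frac,gamma_admixture numeric in (0,1).
#' @export
AdmixtureModelParams <- function(ratio_old_now, n_cr_now, n_ancestral,
                                 n_western, t_divergence, t_bottleneck,
                                 t_admixture_frac, gamma_admixture, mu) {
  new("AdmixtureModelParams", ratio_old_now = ratio_old_now,
      n_cr_now = n_cr_now, n_ancestral = n_ancestral, n_western = n_western,
      t_divergence = t_divergence, t_bottleneck = t_bottleneck,
      t_admixture_frac = t_admixture_frac, gamma_admixture = gamma_admixture,
      mu = mu)
}

# marginal prior specification (study priors)
priorSpec <- function(model = c("im", "admixture")) {
  model <- match.arg(model)
  common <- list(
    ratio_old_now = list(type = "logunif", lo = 1, hi = 100),
    n_cr_now      = list(type = "truncnorm", mean = 200, sd = 100, lo = 68, hi = 300),
    n_ancestral   = list(type = "unif", lo = 500, hi = 25000),
    n_western     = list(type = "truncnorm", mean = 24000, sd = 5000, lo = 10000, hi = 30000),
    t_divergence  = list(type = "logunif", lo = 10, hi = 3162),
    t_bottleneck  = list(type = "logunif", lo = 10, hi = 316),
    mu            = list(type = "truncnorm", mean = 4e-4, sd = 1e-4, lo = 2e-4, hi = 6e-4))
  if (model == "im") {
    c(list(two_Nm = list(type = "logunif", lo = 1, hi = 15.85)),
      common,
      list(t_migration = list(type = "logunif", lo = 10, hi = 3162)))
  } else {
    c(common,
      list(t_admixture_frac = list(type = "unif", lo = 0, hi = 1),
           gamma_admixture = list(type = "unif", lo = 0, hi = 1)))
  }
}

# log density of a loguniform(lo,hi) variate on the natural scale
dnormLogunif <- function(x, lo, hi) {
  -log(x) - log(log(hi) - log(lo))
}

drawMarginal <- function(spec, n) {
  switch(spec$type,
    logunif = 10^runif(n, log10(spec$lo), log10(spec$hi)),
    unif = runif(n, spec$lo, spec$hi),
    truncnorm = {
      plo <- pnorm(spec$lo, spec$mean, spec$sd)
      phi <- pnorm(spec$hi, spec$mean, spec$sd)
      qnorm(runif(n, plo, phi), spec$mean, spec$sd)
    },
    stop("unknown prior type"))
}

#' Draw demographic parameters from the study priors
#'
#' Draws each parameter from its marginal prior (Table of priors: loguniform
#' for `two_Nm`, `ratio_old_now` and the three times; uniform for
#' `n_ancestral` and the admixture fraction/intensity; truncated normal for
#' `n_cr_now`, `n_western` and `mu`) and rejects draws violating the ordering
#' constraints `t_migration <= t_divergence` and
#' `t_bottleneck <= t_divergence`.
#'
#' @param n number of draws.
#' @param model `"im"` or `"admixture"`.
#' @param seed optional integer seed.
#' @return A data.frame with one row per accepted draw (natural scale).
#' @export
samplePrior <- function(n = 1, model = c("im", "admixture"), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  spec <- priorSpec(model)
  draws <- as.data.frame(lapply(spec, drawMarginal, n = n))
  ok <- priorConstraintsOk(draws, model)
  tries <- 0L
  while (!all(ok)) {
    bad <- which(!ok)
    tries <- tries + length(bad)
    if (tries > 1e6) stop("prior rejection loop exceeded 1e6 redraws")
    redraw <- as.data.frame(lapply(spec, drawMarginal, n = length(bad)))
    draws[bad, ] <- redraw
    ok[bad] <- priorConstraintsOk(draws[bad, , drop = FALSE], model)
  }
  draws
}

priorConstraintsOk <- function(df, model) {
  ok <- df$t_bottleneck <= df$t_divergence
  if (model == "im") ok <- ok & df$t_migration <= df$t_divergence
  ok
}

# which parameters are estimated on the log10 scale: the loguniform-prior
# parameters, plus n_ancestral, whose 50-fold uniform prior range makes the
# summary-parameter relation log-linear (the Jacobian of its uniform prior
# is accounted for in priorLogDensity)
log10Params <- function(model) {
  if (model == "im")
    c(two_Nm = TRUE, ratio_old_now = TRUE, n_cr_now = FALSE,
      n_ancestral = TRUE, n_western = FALSE, t_divergence = TRUE,
      t_bottleneck = TRUE, t_migration = TRUE, mu = FALSE)
  else
    c(ratio_old_now = TRUE, n_cr_now = FALSE, n_ancestral = TRUE,
      n_western = FALSE, t_divergence = TRUE, t_bottleneck = TRUE,
      t_admixture_frac = FALSE, gamma_admixture = FALSE, mu = FALSE)
}

# natural-scale data.frame -> estimation-scale matrix (log10 where loguniform)
transformParams <- function(df, model) {
  lg <- log10Params(model)
  df <- df[names(lg)]
  m <- as.matrix(df)
  m[, lg] <- log10(m[, lg, drop = FALSE])
  m
}

backTransform <- function(x, name, model) {
  if (log10Params(model)[[name]]) 10^x else x
}

# prior support on the estimation scale, rows in estimation-column order
priorSupport <- function(model) {
  spec <- priorSpec(model)
  lg <- log10Params(model)
  spec <- spec[names(lg)]
  t(vapply(names(spec), function(nm) {
    b <- c(spec[[nm]]$lo, spec[[nm]]$hi)
    if (lg[[nm]]) log10(b) else b
  }, numeric(2)))
}

# normalized joint log prior density on the estimation scale (rows of theta)
priorLogDensity <- function(theta, model) {
  spec <- priorSpec(model)
  lg <- log10Params(model)
  ld <- rep(-log(priorConstraintMass(model)), nrow(theta))
  for (nm in names(spec)) {
    s <- spec[[nm]]
    x <- theta[, nm]
    onLog <- lg[[nm]]
    # density on the estimation scale: natural-scale density times the
    # Jacobian |d(natural)/d(log10)| = 10^x * ln(10) where log-scaled
    xn <- if (onLog) 10^x else x
    inside <- xn >= s$lo - 1e-12 * abs(s$lo) & xn <= s$hi + 1e-12 * abs(s$hi)
    ln <- switch(s$type,
      logunif = dnormLogunif(xn, s$lo, s$hi),
      unif = rep(-log(s$hi - s$lo), length(xn)),
      truncnorm = {
        Z <- pnorm(s$hi, s$mean, s$sd) - pnorm(s$lo, s$mean, s$sd)
        dnorm(xn, s$mean, s$sd, log = TRUE) - log(Z)
      })
    if (onLog) ln <- ln + log(xn) + log(log(10))
    ld <- ld + ifelse(inside, ln, -Inf)
  }
  # ordering constraints (comparisons are scale-equivariant)
  tb <- theta[, "t_bottleneck"]; td <- theta[, "t_divergence"]
  ld[tb > td] <- -Inf
  if (model == "im") {
    tm <- theta[, "t_migration"]
    ld[tm > td] <- -Inf
  }
  ld
}

# probability that independent marginal draws satisfy the ordering
# constraints (closed form under the loguniform time priors)
priorConstraintMass <- function(model) {
  # v = log10 t_div ~ U[1, 3.5]; u_bot ~ U[1, 2.5]; u_mig ~ U[1, 3.5]
  pBot <- function(v) (pmin(v, 2.5) - 1) / 1.5
  f <- if (model == "im") function(v) pBot(v) * (v - 1) / 2.5 else pBot
  integrate(function(v) f(v) / 2.5, 1, 3.5, rel.tol = 1e-10)$value
}
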