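test_that("per-locus summary arithmetic and translation invariance", {
  loc <- list(g1 = c(10L, 12L), g2 = c(11L, 11L, 14L), g3 = c(9L, 13L))
  s <- perLocusSummaries(loc)
  expect_equal(unname(s), c(2, 3, 8, -1, 0, 1))
  same <- lapply(loc, function(v) v + 7L)
  expect_equal(perLocusSummaries(same), s)
  allEq <- list(g1 = c(5L, 5L), g2 = c(5L, 5L), g3 = c(5L, 5L))
  expect_equal(unname(perLocusSummaries(allEq)), rep(0, 6))
  expect_error(perLocusSummaries(list(g1 = integer(0), g2 = 1L, g3 = 1L)),
               "g1")
  oneAllele <- perLocusSummaries(list(g1 = 5L, g2 = c(5L, 6L), g3 = c(5L, 6L)))
  expect_true(is.na(oneAllele[["var_1"]]))
})

test_that("reference tables are reproducible and stay in prior support", {
  r1 <- buildReferenceTable("im", nSims = 150, seed = 5)
  r2 <- buildReferenceTable("im", nSims = 150, seed = 5)
  expect_identical(r1@params, r2@params)
  expect_identical(r1@summaries, r2@summaries)
  spec <- driftABC:::priorSpec("im")
  for (nm in names(spec))
    expect_true(all(r1@params[[nm]] >= spec[[nm]]$lo &
                    r1@params[[nm]] <= spec[[nm]]$hi))
  expect_error(buildReferenceTable("im", nSims = 10), "nSims")
})

test_that("mode and HDI from a Gaussian sample match the closed form", {
  set.seed(2)
  z <- rnorm(1e5)
  r <- posteriorModeHdi(z, levels = c(0.5, 0.95), support = c(-5, 5))
  expect_lt(abs(r$mode), 0.08)
  expect_lt(abs(r$hdi[["0.95"]][1] + 1.96), 0.05)
  expect_lt(abs(r$hdi[["0.95"]][2] - 1.96), 0.05)
  expect_lt(abs(r$hdi[["0.5"]][2] - 0.674), 0.05)
})

test_that("HDI degenerate inputs: point mass and flat density", {
  r <- posteriorModeHdi(rep(3.2, 600), levels = 0.9)
  expect_equal(r$mode, 3.2)
  expect_equal(unname(r$hdi[["0.9"]]), c(3.2, 3.2))
  set.seed(3)
  u <- runif(2e4)
  ru <- posteriorModeHdi(u, levels = 0.5, support = c(0, 1))
  w <- diff(ru$hdi[["0.5"]])
  expect_lt(abs(w - 0.5), 0.08)  # interval carries the requested mass
  mid <- mean(ru$hdi[["0.5"]])
  expect_lt(abs(mid - 0.5), 0.1)  # tie broken by centering
  expect_error(posteriorModeHdi(rnorm(100)), "500")
  expect_error(posteriorModeHdi(rnorm(600), levels = 1.2), "levels")
})

refIm <- buildReferenceTable("im", nSims = 4000, seed = 42)
obsIm <- t(vapply(simulateDataset(studyModeParams(), kLoci = 8, seed = 7),
                  perLocusSummaries, numeric(6)))

test_that("posterior: HDI nesting, mode containment, prior support", {
  post <- abcGlmPosterior(refIm, obsIm, retainFraction = 0.1,
                          nPosterior = 6000, seed = 9)
  h50 <- posteriorHdi(post, 0.5); h90 <- posteriorHdi(post, 0.9)
  h95 <- posteriorHdi(post, 0.95)
  m <- posteriorMode(post)
  sup <- driftABC:::priorSupport("im")
  lg <- driftABC:::log10Params("im")
  for (p in post@parameters) {
    expect_lte(h50[p, 1], m[p]); expect_gte(h50[p, 2], m[p])
    expect_lte(h90[p, 1], h50[p, 1]); expect_gte(h90[p, 2], h50[p, 2])
    expect_lte(h95[p, 1], h90[p, 1]); expect_gte(h95[p, 2], h90[p, 2])
    nat <- if (lg[[p]]) 10^sup[p, ] else sup[p, ]
    expect_gte(h95[p, 1], nat[1] - 1e-6 * abs(nat[1]))
    expect_lte(h95[p, 2], nat[2] + 1e-6 * abs(nat[2]))
  }
  # no posterior mass outside the prior support
  w <- post@weights
  inSup <- rep(TRUE, nrow(post@theta))
  for (j in seq_along(post@parameters))
    inSup <- inSup & post@theta[, j] >= sup[j, 1] - 1e-9 &
      post@theta[, j] <= sup[j, 2] + 1e-9
  expect_equal(sum(w[!inSup]), 0)
  # posterior quantile is a proper CDF value
  q <- posteriorQuantile(post, "n_cr_now", 200)
  expect_true(q >= 0 && q <= 1)
  expect_error(posteriorQuantile(post, "nope", 1), "unknown")
})

test_that("posterior input validation", {
  expect_error(abcGlmPosterior(refIm, obsIm[, 1:4]), "dimension")
  expect_error(abcGlmPosterior(refIm, obsIm, retainFraction = 0), "retain")
})

test_that("Bayes factors: antisymmetry and null equivalence", {
  refAdm <- buildReferenceTable("admixture", nSims = 4000, seed = 43)
  ab <- bayesFactor(refIm, refAdm, obsIm, retainedCounts = c(200, 400),
                    nMarginal = 8000, seed = 3)
  ba <- bayesFactor(refAdm, refIm, obsIm, retainedCounts = c(200, 400),
                    nMarginal = 8000, seed = 3)
  expect_lt(abs(ab@log10bf + ba@log10bf), 0.25)
  expect_equal(ab@curve$retained, c(200, 400))
  # identical "models" on both sides: log10 BF ~ 0 up to Monte Carlo noise
  self <- bayesFactor(refIm, refIm, obsIm, retainedCounts = 400,
                      nMarginal = 8000, seed = 4)
  expect_lt(abs(self@log10bf), 0.15)
  expect_error(bayesFactor(refIm, refAdm, obsIm[, 1:3]), "dimension")
})

test_that("validation machinery records quantiles and clamping", {
  val <- validateInference(refIm, nPods = 10, kLoci = 4,
                           nPosterior = 4000, seed = 6)
  expect_equal(dim(val$quantiles), c(10L, 9L))
  expect_true(all(val$quantiles >= 0 & val$quantiles <= 1))
  expect_true(all(c("ksP", "meanRelBiasMode", "nClampedModes") %in%
                  names(val$report)))
  expect_true(val$coverage90 >= 0 && val$coverage90 <= 1)
  expect_error(validateInference(refIm, nPods = 5), "nPods")
})
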