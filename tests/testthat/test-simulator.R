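test_that("prior draws respect bounds, loguniform shape and ordering", {
  set.seed(42)
  pr <- samplePrior(20000, "im")
  spec <- driftABC:::priorSpec("im")
  for (nm in names(spec))
    expect_true(all(pr[[nm]] >= spec[[nm]]$lo & pr[[nm]] <= spec[[nm]]$hi),
                label = nm)
  expect_true(all(pr$t_migration <= pr$t_divergence))
  expect_true(all(pr$t_bottleneck <= pr$t_divergence))
  # log10(t_divergence) uniform on [1, 3.5]: compare against the
  # constraint-adjusted CDF (t_div is the larger of constrained draws)
  adm <- samplePrior(20000, "admixture", seed = 7)
  expect_true(all(adm$gamma_admixture > 0 & adm$gamma_admixture < 1))
  expect_true(all(adm$t_admixture_frac > 0 & adm$t_admixture_frac < 1))
  # unconstrained marginals stay loguniform: two_Nm
  ks <- suppressWarnings(ks.test(log10(pr$two_Nm), "punif", 0, log10(15.85)))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero mutation rate returns the root size everywhere", {
  set.seed(1)
  out <- simulateLocus(singleDemeParams(100, 0), samplingScheme("western", 30, 0))
  expect_true(all(out[[1]] == 100))
  out50 <- simulateLocus(singleDemeParams(100, 0),
                         samplingScheme("western", 10, 0), rootSize = 50)
  expect_true(all(out50[[1]] == 50))
})

test_that("datasets are reproducible for a fixed seed and k = 1 reduces", {
  p <- studyModeParams()
  d1 <- simulateDataset(p, kLoci = 3, seed = 9)
  d2 <- simulateDataset(p, kLoci = 3, seed = 9)
  expect_identical(d1, d2)
  set.seed(4); l1 <- simulateDataset(p, kLoci = 1)[[1]]
  set.seed(4); l2 <- simulateLocus(p)
  expect_identical(l1, l2)
  expect_equal(lengths(l2), c(crossriver_historical = 14L,
                              crossriver_modern = 71L, western_modern = 92L))
})

test_that("root translation shifts alleles without changing summaries", {
  p <- studyModeParams()
  set.seed(77); a <- simulateLocus(p, rootSize = 100)
  set.seed(77); b <- simulateLocus(p, rootSize = 50)
  expect_identical(lapply(a, function(v) v - 50L), b)
  expect_equal(perLocusSummaries(a), perLocusSummaries(b))
})

test_that("pairwise coalescence times follow the single-deme expectation", {
  set.seed(42)
  p <- singleDemeParams(200, 0)
  sc <- samplingScheme("western", 2, 0)
  t2 <- replicate(6000, simulateLocus(p, sc, details = TRUE)$coalTimes)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 400), 4 * se)
  # serial sampling shifts the expectation by the sampling gap
  scSer <- samplingScheme(c("western", "western"), c(1, 1), c(0, 11))
  tSer <- replicate(4000, simulateLocus(p, scSer, details = TRUE)$coalTimes)
  expect_lt(abs(mean(tSer) - 411), 4 * sd(tSer) / sqrt(length(tSer)))
})

test_that("two-deme IM coalescence times match the analytic Markov chain", {
  # exact 3-state structured-coalescent law for two lineages, constant sizes
  N0 <- 150; N1 <- 300; M <- 2
  m0 <- M / (2 * N0); m1 <- M / (2 * N1)
  Q <- rbind(c(-(m0 + m1), m1, m0),                     # D: one per deme
             c(2 * m0, -(2 * m0 + 1 / (2 * N0)), 0),    # S0: both focal
             c(2 * m1, 0, -(2 * m1 + 1 / (2 * N1))))    # S1: both outgroup
  cdfD <- function(t) {
    vapply(t, function(tt) {
      P <- Matrix::expm(Q * tt)
      1 - sum(P[1, ])
    }, numeric(1))
  }
  p <- IMModelParams(two_Nm = M, ratio_old_now = 1, n_cr_now = N0,
                     n_ancestral = N0, n_western = N1, t_divergence = 1e9,
                     t_bottleneck = 0, t_migration = 0, mu = 0)
  sc <- samplingScheme(c("crossriver", "western"), c(1, 1), c(0, 0))
  set.seed(42)
  t2 <- replicate(5000, simulateLocus(p, sc, details = TRUE)$coalTimes)
  ks <- suppressWarnings(ks.test(t2, cdfD))
  expect_gt(ks$p.value, 0.01)
})

test_that("the admixture model with vanishing gamma reduces to isolation", {
  im0 <- IMModelParams(two_Nm = 0, ratio_old_now = 5, n_cr_now = 200,
                       n_ancestral = 2000, n_western = 5000,
                       t_divergence = 400, t_bottleneck = 50,
                       t_migration = 10, mu = 4e-4)
  adm0 <- AdmixtureModelParams(ratio_old_now = 5, n_cr_now = 200,
                               n_ancestral = 2000, n_western = 5000,
                               t_divergence = 400, t_bottleneck = 50,
                               t_admixture_frac = 0.5,
                               gamma_admixture = 1e-9, mu = 4e-4)
  sc <- defaultSamplingScheme()
  set.seed(42)
  sIm <- t(replicate(600, perLocusSummaries(simulateLocus(im0, sc))))
  sAd <- t(replicate(600, perLocusSummaries(simulateLocus(adm0, sc))))
  for (j in c(1, 4, 6)) {
    ks <- suppressWarnings(ks.test(sIm[, j], sAd[, j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("haploid samples within a group are exchangeable", {
  p <- studyModeParams()
  set.seed(42)
  draws <- t(replicate(500, simulateLocus(p)$crossriver_modern[c(1, 36, 71)]))
  expect_gt(suppressWarnings(ks.test(draws[, 1], draws[, 2]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(draws[, 1], draws[, 3]))$p.value, 0.01)
})

test_that("model parameter validity is enforced", {
  expect_error(IMModelParams(1, 0.5, 200, 1000, 1000, 100, 10, 10, 4e-4),
               "ratio")
  expect_error(IMModelParams(1, 2, 200, 1000, 1000, 100, 10, 200, 4e-4),
               "t_migration")
  expect_error(AdmixtureModelParams(2, 200, 1000, 1000, 100, 10, 1.5, 0.5,
                                    4e-4), "t_admixture_frac")
})
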