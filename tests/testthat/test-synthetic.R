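test_that("study-shaped datasets have the study design", {
  gt <- generateStudyLikeDataset(studyModeParams(), seed = 3)
  expect_equal(nIndividuals(gt), 177L)
  expect_equal(vapply(sampleLabels(gt), function(s) nIndividuals(gt, s),
                      integer(1), USE.NAMES = FALSE), c(14L, 71L, 92L))
  expect_length(lociNames(gt), 8)
  ann <- sampleAnnotation(gt)
  expect_equal(ann$time_bp, c(5L, 0L, 0L))
  expect_equal(ann$deme, c("crossriver", "crossriver", "western"))
})

test_that("mu = 0 and no missingness yield all-homozygous root genotypes", {
  p <- IMModelParams(two_Nm = 1, ratio_old_now = 2, n_cr_now = 100,
                     n_ancestral = 1000, n_western = 1000,
                     t_divergence = 100, t_bottleneck = 10,
                     t_migration = 10, mu = 0)
  gt <- generateStudyLikeDataset(p, kLoci = 2, seed = 5)
  expect_true(all(gt@a1 == 100L) && all(gt@a2 == 100L))
})

test_that("missingness hits the requested per-genotype rate", {
  gt <- generateStudyLikeDataset(studyModeParams(), missingRate = 0.1,
                                 seed = 21)
  obs <- mean(is.na(gt@a1))
  expect_lt(abs(obs - 0.10), 0.02)
  expect_error(generateStudyLikeDataset(studyModeParams(), missingRate = 1),
               "missingRate")
})

test_that("generation is deterministic per seed and writes valid files", {
  g1 <- generateStudyLikeDataset(studyModeParams(), seed = 8)
  g2 <- generateStudyLikeDataset(studyModeParams(), seed = 8)
  expect_identical(g1@a1, g2@a1)
  pre <- tempfile()
  g3 <- generateStudyLikeDataset(studyModeParams(), seed = 8,
                                 outPrefix = pre)
  back <- readGenepop(paste0(pre, ".gen"), paste0(pre, "_samples.txt"))
  expect_identical(g3@a1, back@a1)
})

test_that("temporal WF data reduce to the sampling-only expectation at huge Ne", {
  set.seed(42)
  fcs <- replicate(400, {
    pairs <- generateTemporalWFDataset(1e6, 60, 60, t = 5, kLoci = 1,
                                       nAlleles = 10)
    fcStatistic(pairs)$multilocus
  })
  sampling <- 1 / 60 + 1 / 60
  expect_lt(abs(mean(fcs) - sampling) / sampling, 0.1)
  d1 <- generateTemporalWFDataset(50, 20, 20, 3, kLoci = 2, seed = 4)
  d2 <- generateTemporalWFDataset(50, 20, 20, 3, kLoci = 2, seed = 4)
  expect_identical(d1, d2)
  expect_error(generateTemporalWFDataset(1, 10, 10, 2), "ne")
})

test_that("diploid pairing preserves the haploid summary distribution", {
  p <- studyModeParams()
  set.seed(42)
  fromTables <- t(replicate(300, {
    gt <- generateStudyLikeDataset(p, kLoci = 1)
    observedSummaries(gt)[1, ]
  }))
  raw <- t(replicate(300, perLocusSummaries(simulateLocus(p))))
  for (j in c(1, 3, 5)) {
    ks <- suppressWarnings(ks.test(fromTables[, j], raw[, j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("synthetic data flow through every pipeline stage", {
  gt <- generateStudyLikeDataset(studyModeParams(), missingRate = 0.03,
                                 seed = 12)
  f <- tempfile(fileext = ".gen"); a <- tempfile()
  writeGenepop(gt, f, annotationPath = a)
  gt2 <- readGenepop(f, a)
  rep2 <- diversityReport(gt2, samples = c("crossriver_historical",
                                           "crossriver_modern"),
                          nPerm = 30, seed = 1)
  expect_true(is.finite(rep2$fst))
  hr <- heResamplingTest(gt2, gt2, reps = 100, seed = 2,
                         modernSample = "crossriver_modern",
                         historicalSample = "crossriver_historical")
  expect_true(hr$fraction >= 0 && hr$fraction <= 1)
  pairs <- temporalPairsFromTable(gt2, "crossriver_modern",
                                  "crossriver_historical")
  expect_equal(attr(pairs, "t"), 5L)
  ne <- temporalNe(pairs, plan = 1)
  expect_true(nePoint(ne) > 0)
  obs <- observedSummaries(gt2, seed = 3)
  expect_equal(ncol(obs), 6)
  expect_true(nrow(obs) >= 6)
})
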