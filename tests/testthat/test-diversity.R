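test_that("observed heterozygosity counts heterozygous individuals", {
  gt <- makeTable(cbind(c(10L, 10L, 12L, 10L)), cbind(c(12L, 10L, 12L, 12L)),
                  pop = rep("s", 4))
  expect_equal(unname(observedHeterozygosity(gt, "s")$perLocus), 0.5)
  hom <- makeTable(cbind(c(10L, 12L)), cbind(c(10L, 12L)), pop = c("s", "s"))
  expect_equal(observedHeterozygosity(hom, "s")$mean, 0)
})

test_that("Nei's unbiased expected heterozygosity", {
  gt <- makeTable(cbind(c(12L, 12L)), cbind(c(14L, 12L)), pop = c("s", "s"))
  he <- unbiasedExpectedHeterozygosity(alleleFrequencies(gt, "s"))
  expect_equal(unname(he$perLocus), 0.5)  # (4/3)(1 - 0.625)
  mono <- makeTable(cbind(c(9L, 9L)), cbind(c(9L, 9L)), pop = c("s", "s"))
  expect_equal(unname(unbiasedExpectedHeterozygosity(
    alleleFrequencies(mono, "s"))$perLocus), 0)
  # large-n limit at p = (0.5, 0.5) approaches 0.5
  n <- 5000
  big <- makeTable(matrix(rep(c(10L, 12L), n / 2), n, 1),
                   matrix(rep(c(10L, 12L), n / 2), n, 1), pop = rep("s", n))
  expect_equal(unbiasedExpectedHeterozygosity(
    alleleFrequencies(big, "s"))$mean, 0.5, tolerance = 1e-3)
})

test_that("allelic richness rarefaction identities", {
  expect_equal(allelicRichness(c(a = 2, b = 2), 2), 5 / 3)
  expect_equal(allelicRichness(c(a = 3, b = 5, c = 2), 10), 3)  # g = N
  expect_equal(allelicRichness(c(a = 7), 3), 1)                 # monomorphic
  expect_error(allelicRichness(c(a = 2), 3, locus = "L9"), "L9")
})

test_that("allelic richness is monotone non-decreasing in g", {
  set.seed(8)
  for (r in 1:20) {
    counts <- table(sample(1:6, 30, replace = TRUE))
    ar <- vapply(1:30, function(g) allelicRichness(counts, g), numeric(1))
    expect_true(all(diff(ar) >= -1e-12))
  }
})

test_that("W&C F_IS matches a brute-force variance-component oracle", {
  # independent oracle: direct transcription of the r = 1 components
  oracleFis <- function(a1, a2) {
    B <- C <- 0
    for (j in seq_len(ncol(a1))) {
      x1 <- a1[, j]; x2 <- a2[, j]
      ok <- !is.na(x1); x1 <- x1[ok]; x2 <- x2[ok]
      n <- length(x1)
      alleles <- unique(c(x1, x2))
      if (length(alleles) < 2) next
      for (al in alleles) {
        cnt <- (x1 == al) + (x2 == al)
        p <- sum(cnt) / (2 * n)
        h <- mean(cnt == 1)
        B <- B + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
        C <- C + h / 2
      }
    }
    1 - C / (B + C)
  }
  # Hardy-Weinberg-exact counts 1AA:2Aa:1aa: small finite value (= 1/7)
  gt <- makeTable(cbind(c(10L, 10L, 10L, 12L)), cbind(c(10L, 12L, 12L, 12L)),
                  pop = rep("s", 4))
  f <- fIS(gt, "s")
  expect_equal(f$multilocus, oracleFis(gt@a1, gt@a2))
  expect_equal(f$multilocus, 1 / 7)
  # random tables agree with the oracle
  set.seed(13)
  for (r in 1:10) {
    rt <- randomTable(nInd = 10, nLoci = 3, nPop = 1, missingRate = 0.1)
    expect_equal(fIS(rt, sampleLabels(rt))$multilocus,
                 oracleFis(rt@a1, rt@a2))
  }
  # all homozygous at a polymorphic locus
  hom <- makeTable(cbind(c(10L, 12L, 10L)), cbind(c(10L, 12L, 10L)),
                   pop = rep("s", 3))
  expect_equal(fIS(hom, "s")$multilocus, 1)
})

test_that("W&C F_ST: fixed differences give theta = 1, null gives ~0", {
  a <- makeTable(cbind(rep(c(10L, 20L), each = 4)),
                 cbind(rep(c(10L, 20L), each = 4)),
                 pop = rep(c("A", "B"), each = 4))
  expect_equal(fST(a, "A", "B", nPerm = 9, seed = 1)$theta, 1)
  set.seed(3)
  nul <- randomTable(nInd = 30, nLoci = 5, nPop = 2, missingRate = 0)
  th <- fST(nul, "pop1", "pop2", nPerm = 99, seed = 2)
  expect_lt(abs(th$theta), 0.05)
  expect_gt(th$p, 0.05)
  one <- makeTable(cbind(c(10L, 11L, 10L)), cbind(c(10L, 11L, 12L)),
                   pop = c("A", "A", "B"))
  expect_error(fST(one, "A", "B"), "at least 2")
})

test_that("F_ST matches an independent two-population variance-component oracle", {
  oracleTheta <- function(a1, a2, grp) {
    SA <- SABC <- 0
    for (j in seq_len(ncol(a1))) {
      x1 <- a1[, j]; x2 <- a2[, j]
      n_i <- c(sum(grp == 1), sum(grp == 2))
      r <- 2; nbar <- mean(n_i); nsum <- sum(n_i)
      nc <- nsum - sum(n_i^2) / nsum
      alleles <- unique(c(x1, x2))
      if (length(alleles) < 2) next
      for (al in alleles) {
        cnt <- (x1 == al) + (x2 == al)
        p_i <- c(sum(cnt[grp == 1]), sum(cnt[grp == 2])) / (2 * n_i)
        h_i <- c(mean(cnt[grp == 1] == 1), mean(cnt[grp == 2] == 1))
        pbar <- sum(n_i * p_i) / nsum
        hbar <- sum(n_i * h_i) / nsum
        s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
        inner <- pbar * (1 - pbar) - s2 / 2
        a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
        SA <- SA + a; SABC <- SABC + a + b + hbar / 2
      }
    }
    SA / SABC
  }
  set.seed(17)
  for (r in 1:8) {
    gt <- randomTable(nInd = 14, nLoci = 2, nPop = 2, missingRate = 0)
    grp <- ifelse(gt@pop == "pop1", 1L, 2L)
    expect_equal(fST(gt, "pop1", "pop2", nPerm = 1, seed = 1)$theta,
                 oracleTheta(gt@a1, gt@a2, grp))
  }
})

test_that("F_ST permutation p-values are super-uniform under the null", {
  set.seed(29)
  pvals <- replicate(400, {
    hap <- matrix(sample(8:13, 24 * 4, replace = TRUE), 24)
    gt <- makeTable(hap, matrix(sample(8:13, 24 * 4, replace = TRUE), 24),
                    pop = rep(c("A", "B"), each = 12))
    fST(gt, "A", "B", nPerm = 60)$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)  # no evidence of anti-conservatism
})

test_that("He resampling test equals exhaustive enumeration on a tiny case", {
  set.seed(41)
  mod <- randomTable(nInd = 6, nLoci = 3, nPop = 1, missingRate = 0)
  hist <- randomTable(nInd = 3, nLoci = 3, nPop = 1, missingRate = 0)
  heHist <- unbiasedExpectedHeterozygosity(
    alleleFrequencies(hist, sampleLabels(hist)))$mean
  subsets <- combn(6, 3)
  exact <- mean(apply(subsets, 2, function(idx)
    driftABC:::meanHeOfRows(mod, idx)) >= heHist)
  est <- heResamplingTest(mod, hist, reps = 4000, seed = 7)$fraction
  expect_lt(abs(est - exact), 0.03)
  expect_error(heResamplingTest(mod, hist, reps = 0), "reps")
  expect_error(heResamplingTest(hist, mod), "smaller")
})

test_that("He resampling fractions are roughly uniform under the null", {
  set.seed(53)
  mod <- randomTable(nInd = 40, nLoci = 6, nPop = 1, missingRate = 0)
  fracs <- vapply(1:150, function(s) {
    idx <- sample(40, 10)
    hist <- makeTable(mod@a1[idx, ], mod@a2[idx, ], pop = rep("h", 10))
    heResamplingTest(mod, hist, reps = 120, seed = s)$fraction
  }, numeric(1))
  ks <- suppressWarnings(ks.test(fracs, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("diversity report assembles all statistics for two samples", {
  set.seed(61)
  gt <- randomTable(nInd = 24, nLoci = 4, nPop = 2, missingRate = 0.05)
  rep2 <- diversityReport(gt, nPerm = 49, seed = 1)
  expect_named(rep2$samples, c("pop1", "pop2"))
  df <- rep2$samples$pop1
  expect_true(all(df$Ho >= 0 & df$Ho <= 1, na.rm = TRUE))
  expect_true(all(df$He >= 0 & df$He <= 1, na.rm = TRUE))
  expect_true(all(df$AR >= 1, na.rm = TRUE))
  expect_true(rep2$fst >= -1 && rep2$fst <= 1)
  expect_true(rep2$fstP > 0 && rep2$fstP <= 1)
})
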