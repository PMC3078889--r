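test_that("Fc arithmetic, degenerate cases and elementwise oracle", {
  p <- temporalPair(c(a = 0.5, b = 0.5), c(a = 0.75, b = 0.25), 40, 40)
  expect_equal(fcStatistic(p)$multilocus, 0.25)
  same <- temporalPair(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7), 10, 10)
  expect_equal(fcStatistic(same)$multilocus, 0)
  mono <- temporalPair(c(a = 1), c(a = 1), 10, 10)
  fc <- fcStatistic(list(m = mono, p = p))
  expect_equal(fc$excluded, "m")
  expect_equal(unname(fc$perLocus["p"]), 0.25)
  # brute-force oracle on random frequency pairs
  set.seed(19)
  for (r in 1:20) {
    A <- sample(2:6, 1)
    x <- rexp(A); x <- x / sum(x); y <- rexp(A); y <- y / sum(y)
    names(x) <- names(y) <- letters[1:A]
    pr <- temporalPair(x, y, 50, 50)
    manual <- mean(vapply(seq_len(A), function(i)
      (x[i] - y[i])^2 / ((x[i] + y[i]) / 2 - x[i] * y[i]), numeric(1)))
    expect_equal(fcStatistic(pr)$multilocus, manual)
  }
})

test_that("Fk arithmetic and the biallelic Fc/Fk closed-form relation", {
  p <- temporalPair(c(a = 0.5, b = 0.5), c(a = 0.75, b = 0.25), 40, 40)
  expect_equal(fkStatistic(p)$multilocus, 0.0625 / 0.625 + 0.0625 / 0.375)
  # biallelic: Fk = Fc * (s/2 - xy) * 4 / (s (2 - s)), s = x + y
  set.seed(23)
  for (r in 1:20) {
    x <- runif(1, 0.05, 0.95); y <- runif(1, 0.05, 0.95)
    pr <- temporalPair(c(a = x, b = 1 - x), c(a = y, b = 1 - y), 30, 30)
    s <- x + y
    ratio <- (s / 2 - x * y) * 4 / (s * (2 - s))
    expect_equal(fkStatistic(pr)$multilocus,
                 fcStatistic(pr)$multilocus * ratio)
  }
})

test_that("multilocus statistics are invariant to relabeling and locus order", {
  set.seed(27)
  pairs <- generateTemporalWFDataset(100, 40, 40, 4, kLoci = 5, nAlleles = 6)
  shuffled <- rev(lapply(pairs, function(p) {
    perm <- sample(length(p$x))
    list(x = setNames(p$x[perm], letters[seq_along(perm)]),
         y = setNames(p$y[perm], letters[seq_along(perm)]),
         n0 = p$n0, nt = p$nt)
  }))
  attr(shuffled, "t") <- attr(pairs, "t")
  expect_equal(fcStatistic(pairs)$multilocus, fcStatistic(shuffled)$multilocus)
  expect_equal(fkStatistic(pairs)$multilocus, fkStatistic(shuffled)$multilocus)
  expect_equal(nePoint(temporalNe(pairs, plan = 1)),
               nePoint(temporalNe(shuffled, plan = 1)))
})

test_that("moment inversion of F: arithmetic, infinity, plan-1 domain", {
  ne <- neFromTemporalF(0.25, 50, 50, t = 5, plan = 2)
  expect_equal(nePoint(ne), 5 / (2 * 0.23), tolerance = 1e-12)
  # all change explained by sampling -> infinite estimate
  expect_equal(nePoint(neFromTemporalF(1 / 100 + 1 / 100, 50, 50, t = 5,
                                       plan = 2)), Inf)
  expect_error(neFromTemporalF(0.2, 50, 50, t = 2, plan = 1), "plan 1")
  expect_error(neFromTemporalF(-0.1, 50, 50, t = 5), "positive")
  # chi-square bounds bracket the point estimate
  withCI <- neFromTemporalF(0.25, 50, 50, t = 5, plan = 2, df = 40)
  b <- neBounds(withCI)
  expect_lte(b["lower"], nePoint(withCI))
  expect_gte(b["upper"], nePoint(withCI))
  # weak signal: upper bound opens to infinity
  weak <- neFromTemporalF(0.0205, 50, 50, t = 5, plan = 2, df = 10)
  expect_equal(unname(neBounds(weak)["upper"]), Inf)
})

test_that("rare-allele pooling merges small classes and keeps mass", {
  p <- temporalPair(c(a = 0.60, b = 0.30, c = 0.06, d = 0.04),
                    c(a = 0.62, b = 0.28, c = 0.04, d = 0.06), 50, 50)
  pooled <- poolRareAlleles(list(L = p), minCopies = 5)
  expect_equal(names(pooled$L$x), c("a", "b", "pooled"))
  expect_equal(unname(pooled$L$x[["pooled"]]), 0.10)
  expect_equal(sum(pooled$L$x), 1)
  expect_equal(sum(pooled$L$y), 1)
  # a single rare allele is left alone (nothing to pool it with)
  one <- temporalPair(c(a = 0.55, b = 0.40, c = 0.05),
                      c(a = 0.55, b = 0.41, c = 0.04), 50, 50)
  expect_equal(poolRareAlleles(list(L = one))$L, one)
  # common alleles are never touched
  com <- temporalPair(c(a = 0.5, b = 0.5), c(a = 0.4, b = 0.6), 50, 50)
  expect_equal(poolRareAlleles(list(L = com))$L, com)
})

test_that("plan 1 equals plan 2 rescaled by (t-2)/t", {
  p2 <- nePoint(neFromTemporalF(0.3, 40, 60, t = 5, plan = 2))
  p1 <- nePoint(neFromTemporalF(0.3, 40, 60, t = 5, plan = 1))
  expect_equal(p1 / p2, 3 / 5)
})
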