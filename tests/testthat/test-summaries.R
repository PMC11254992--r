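# Heritability arithmetic, scale conversion, HPD intervals,
# null-hypothesis evidence, Heidelberger-Welch diagnostic.

makePosterior <- function(vd) {
  new("PosteriorSamples",
      varianceDraws = vd, effectDraws = matrix(0, nrow(vd), 1),
      liabilityDraws = matrix(0, 0, 0), effectBlocks = 0L,
      meta = list(blocks = setdiff(colnames(vd), "residual")))
}

test_that("per-draw heritability follows the variance-component ratio", {
  vd <- matrix(rep(c(1, 1, 1, 1), each = 12), ncol = 4,
               dimnames = list(NULL, c("individual", "family", "generation", "residual")))
  ps <- makePosterior(vd)
  est <- heritabilityFromSamples(ps, includeResidual = TRUE)
  expect_equal(est@h2Liability, 0.25)

  vd2 <- matrix(rep(c(2, 0, 0, 1), each = 12), ncol = 4,
                dimnames = list(NULL, c("individual", "family", "generation", "residual")))
  est2 <- heritabilityFromSamples(makePosterior(vd2), includeResidual = FALSE)
  expect_equal(est2@h2Liability, 1) # components-only denominator, degenerate

  vd3 <- matrix(rep(c(99, 0, 0, 1), each = 12), ncol = 4,
                dimnames = list(NULL, c("individual", "family", "generation", "residual")))
  est3 <- heritabilityFromSamples(makePosterior(vd3), includeResidual = TRUE)
  expect_equal(est3@h2Liability, 0.99)
})

test_that("liability/observed conversion is correct, monotone and invertible", {
  expect_equal(liabilityToObserved(0, 0.3), 0)
  # monotone in h2 and, below 0.5, increasing in prevalence
  h <- seq(0, 1, by = 0.1)
  expect_true(all(diff(liabilityToObserved(h, 0.2)) > 0))
  p <- seq(0.05, 0.45, by = 0.05)
  expect_true(all(diff(liabilityToObserved(0.4, p)) > 0))
  # always a shrinkage for realistic prevalence
  expect_true(all(liabilityToObserved(h[-1], 0.2) < h[-1]))
  # round trip
  for (pp in c(0.056, 0.2, 0.4)) {
    expect_equal(observedToLiability(liabilityToObserved(0.37, pp), pp), 0.37,
                 tolerance = 1e-12)
  }
  expect_error(liabilityToObserved(0.3, 0), "prevalence")
  expect_error(liabilityToObserved(0.3, 1), "prevalence")
})

test_that("HPD interval is the shortest window with documented tie-breaks", {
  expect_equal(hpdInterval(0:999, 0.95), c(lower = 0, upper = 949))
  expect_equal(hpdInterval(rep(3.7, 25), 0.95), c(lower = 3.7, upper = 3.7))
  set.seed(8)
  z <- rnorm(1e5)
  hpd <- hpdInterval(z, 0.95)
  expect_equal(unname(hpd), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  # mass -> 1 converges to the range
  expect_equal(unname(hpdInterval(z, 1 - 1e-9)), range(z))
  expect_error(hpdInterval(1:5), "10")
})

test_that("posterior mean h2 lies inside its own HPD and in [0, 1]", {
  set.seed(9)
  vd <- cbind(individual = rchisq(500, 3), family = rchisq(500, 2),
              generation = rchisq(500, 1), residual = 1)
  est <- heritabilityFromSamples(makePosterior(vd), includeResidual = TRUE,
                                 prevalence = 0.15)
  h2 <- attr(est, "h2Draws")
  expect_true(all(h2 >= 0 & h2 <= 1))
  expect_gte(est@h2Liability, est@hpdLiability[1])
  expect_lte(est@h2Liability, est@hpdLiability[2])
  expect_gte(est@h2Observed, est@hpdObserved[1])
  expect_lte(est@h2Observed, est@hpdObserved[2])
  expect_lte(est@h2Observed, est@h2Liability) # prevalence < 0.5
})

test_that("null-heritability evidence summaries behave at both extremes", {
  set.seed(10)
  strong <- 0.2 + 0.1 * abs(rnorm(500))
  ev <- h2NullEvidence(strong)
  expect_equal(ev$massBelowEpsilon, 0)
  expect_true(ev$hpdExcludesZero)
  expect_true(ev$reject)

  nullish <- abs(rnorm(500, 0, 0.02))
  ev0 <- h2NullEvidence(nullish)
  expect_false(ev0$reject)
  expect_gt(ev0$massBelowEpsilon, 0.1)
  # conservation of mass
  expect_equal(ev0$massBelowEpsilon + mean(nullish >= 0.01), 1)
  expect_error(h2NullEvidence(strong[1:50]), "100")
})

test_that("stationary iid chains pass Heidelberger-Welch at about the nominal rate", {
  set.seed(11)
  pass <- vapply(1:100, function(i) {
    heidelbergerWelch(rnorm(1000))@stationarityPassed
  }, TRUE)
  # binomial 99% bounds around 0.95 for 100 trials
  expect_gte(sum(pass), 89)

  # agreement with the independent coda implementation on pass/fail
  codaPass <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    x <- rnorm(1000)
    mine <- heidelbergerWelch(x)@stationarityPassed
    ref <- unname(coda::heidel.diag(coda::mcmc(x))[1, "stest"] == 1)
    c(mine = mine, ref = ref)
  }, c(mine = TRUE, ref = TRUE))
  expect_gte(mean(codaPass["mine", ] == codaPass["ref", ]), 0.9)
})

test_that("a strong trend fails stationarity; a constant chain passes", {
  set.seed(12)
  trended <- rnorm(1000) + seq(0, 10, length.out = 1000)
  d <- heidelbergerWelch(trended)
  expect_false(d@stationarityPassed)
  expect_equal(d@fractionDiscarded, 0.5)

  const <- heidelbergerWelch(rep(2, 500))
  expect_true(const@stationarityPassed)
  expect_true(is.na(const@halfwidthPassed)) # not applicable
})

test_that("halfwidth test reflects chain precision", {
  set.seed(13)
  precise <- rnorm(5000, mean = 50, sd = 1)
  expect_true(heidelbergerWelch(precise)@halfwidthPassed)
  noisy <- rnorm(200, mean = 0.01, sd = 5)
  d <- heidelbergerWelch(noisy)
  if (d@stationarityPassed) expect_false(d@halfwidthPassed)
})
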