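# Design construction and Henderson's equations.

test_that("the three presets map to the published effect structures", {
  I <- modelSpec("I")
  expect_setequal(I@fixedEffects, c("intercept", "sex", "family", "generation"))
  expect_equal(I@randomEffects, "individual")
  II <- modelSpec("II")
  expect_setequal(II@fixedEffects, c("intercept", "sex", "generation"))
  expect_setequal(II@randomEffects, c("individual", "family"))
  III <- modelSpec("III")
  expect_setequal(III@fixedEffects, c("intercept", "sex"))
  expect_setequal(III@randomEffects, c("individual", "family", "generation"))
})

test_that("an effect cannot be both fixed and random", {
  expect_error(modelSpec(fixedEffects = c("sex", "family"),
                         randomEffects = c("individual", "family")),
               "both fixed and random")
})

test_that("design matrices have the documented shapes", {
  cfg <- simulationConfig(nFamilies = 3, seed = 8)
  ped <- simulatePhenotypes(simulatePedigree(cfg), cfg)$ped
  n <- nIndividuals(ped)

  sys3 <- buildDesign(ped, modelSpec("III"))
  expect_equal(colnames(sys3@X), c("intercept", "sex_male"))
  expect_equal(names(sys3@Zlist), c("individual", "family", "generation"))
  expect_equal(ncol(sys3@Zlist$individual), n)
  expect_equal(ncol(sys3@Zlist$family), 3L)
  expect_equal(ncol(sys3@Zlist$generation), length(unique(ped@generation)))
  # individual block columns follow the parents-first ordering
  expect_equal(colnames(sys3@Zlist$individual), sortParentsFirst(ped))

  sys1 <- buildDesign(ped, modelSpec("I"))
  expect_equal(names(sys1@Zlist), "individual")
  expect_true(any(grepl("^family_", colnames(sys1@X))))
  expect_true(any(grepl("^generation_", colnames(sys1@X))))
})

test_that("single-level fixed factors are dropped with a warning", {
  ped <- newPedigree(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"),
                     sex = rep("female", 3), phenotype = c(0L, 1L, 0L))
  expect_warning(sys <- buildDesign(ped, modelSpec("III")), "single level")
  expect_equal(colnames(sys@X), "intercept")
})

test_that("intercept-only system without random effects reduces to least squares", {
  ped <- newPedigree(c("a", "b"), c(NA, NA), c(NA, NA), phenotype = c(0L, 1L))
  sys <- buildDesign(ped, modelSpec(fixedEffects = character()))
  sys@Zlist <- list()
  sys@y <- c(1, 2)
  sol <- solveMME(sys, c(residual = 1))
  expect_equal(unname(fixedEstimates(sol)), 1.5)
})

test_that("identity-relationship example matches the closed form", {
  ped <- newPedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3),
                     phenotype = c(0L, 0L, 1L))
  sys <- buildDesign(ped, modelSpec(fixedEffects = character()))
  sys@y <- c(1, 2, 3)
  sol <- solveMME(sys, c(individual = 1))
  expect_equal(unname(fixedEstimates(sol)), 2)
  expect_equal(unname(randomPredictions(sol)$individual), c(-0.5, 0, 0.5))
})

test_that("solveMME equals the dense GLS oracle on random systems", {
  for (seed in 1:6) {
    ped <- randomPedigree(30, seed)
    sys <- buildDesign(ped, modelSpec("III"))
    set.seed(seed + 100)
    sys@y <- rnorm(nIndividuals(ped))
    vc <- c(individual = runif(1, 0.2, 2), family = runif(1, 0.2, 2),
            generation = runif(1, 0.2, 2))
    sol <- solveMME(sys, vc)
    oracle <- glsOracle(sys, vc)
    expect_lt(max(abs(unname(fixedEstimates(sol)) - oracle$beta)), 1e-8)
    for (b in names(oracle$u)) {
      expect_lt(max(abs(unname(randomPredictions(sol)[[b]]) - oracle$u[[b]])), 1e-8)
    }
  }
})

test_that("shrinkage limit: u -> 0 as the genetic variance vanishes", {
  ped <- randomPedigree(25, seed = 3)
  sys <- buildDesign(ped, modelSpec(fixedEffects = "sex"))
  sol <- solveMME(sys, c(individual = 1e-8))
  expect_lt(max(abs(randomPredictions(sol)$individual)), 1e-6)
})

test_that("individual BLUPs sum to ~0 with an intercept and identity A", {
  ped <- newPedigree(sprintf("f%d", 1:12), rep(NA, 12), rep(NA, 12),
                     phenotype = rep(c(0L, 1L), 6))
  sys <- buildDesign(ped, modelSpec(fixedEffects = character()))
  set.seed(4)
  sys@y <- rnorm(12)
  sol <- solveMME(sys, c(individual = 0.7))
  expect_lt(abs(sum(randomPredictions(sol)$individual)), 1e-10)
})

test_that("the solution is invariant to row permutation of individuals", {
  ped <- randomPedigree(20, seed = 9)
  sys <- buildDesign(ped, modelSpec("III"))
  set.seed(5)
  sys@y <- rnorm(20)
  vc <- c(individual = 0.8, family = 0.5, generation = 0.4)
  sol <- solveMME(sys, vc)

  perm <- sample(20)
  ped2 <- subsetPedigreeForTest(ped, perm)
  sys2 <- buildDesign(ped2, modelSpec("III"))
  sys2@y <- sys@y[perm]
  sol2 <- solveMME(sys2, vc)
  u1 <- randomPredictions(sol)$individual
  u2 <- randomPredictions(sol2)$individual
  expect_equal(u2[names(u1)], u1, tolerance = 1e-9)
  expect_equal(fixedEstimates(sol2), fixedEstimates(sol), tolerance = 1e-9)
})

test_that("missing variance components are reported", {
  ped <- randomPedigree(10, seed = 2)
  sys <- buildDesign(ped, modelSpec("III"))
  expect_error(solveMME(sys, c(individual = 1)), "family")
})
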