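# EGV table, parental means, ROC/AUC, group comparison, correlation,
# family prevalence.

test_that("EGV is the posterior mean with IQR of the individual effect draws", {
  ped <- newPedigree(c("a", "b"), c(NA, NA), c(NA, NA),
                     phenotype = c(0L, 1L))
  eff <- cbind(0, c(0.1, 0.3), c(0, 0))
  colnames(eff) <- c("intercept", "individual:a", "individual:b")
  ps <- new("PosteriorSamples",
            varianceDraws = cbind(individual = c(1, 1), residual = 1),
            effectDraws = eff, liabilityDraws = matrix(0, 0, 0),
            effectBlocks = c(0L, 1L, 1L),
            meta = list(blocks = "individual", ids = c("a", "b"),
                        individualOrder = c("a", "b")))
  tab <- egvTable(ps, ped)
  expect_equal(tab$egv, c(0.2, 0))
  expect_equal(tab$egvQ1[2], 0)
  expect_equal(tab$egvQ3[2], 0)
})

test_that("parental-mean predictions follow the inheritance rule", {
  ped <- newPedigree(c("f", "m", "k", "h"), c(NA, NA, "f", "f"),
                     c(NA, NA, "m", NA))
  tab <- data.frame(id = c("f", "m", "k", "h"), egv = c(0.4, 0.2, 0.9, 0.5))
  pred <- parentalMeanEGV(tab, ped)
  expect_equal(pred, c(NA, NA, 0.3, NA)) # founders and single-parent NA
  predHalf <- parentalMeanEGV(tab, ped, singleParentHalf = TRUE)
  expect_equal(predHalf[4], 0.2) # known parent / 2
  # symmetric parents cancel
  ped2 <- newPedigree(c("p", "q", "z"), c(NA, NA, "p"), c(NA, NA, "q"))
  tab2 <- data.frame(id = c("p", "q", "z"), egv = c(0.7, -0.7, 0.1))
  expect_equal(parentalMeanEGV(tab2, ped2)[3], 0)
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.8), c(1, 1, 0, 0))$auc, 0.875)
  expect_equal(rocAuc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1) # separated
  expect_equal(rocAuc(rep(3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5) # all ties
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- rocAuc(scores, labels)
    expect_equal(r$auc, aucOracle(scores, labels))
    # complement symmetry
    expect_equal(rocAuc(-scores, labels)$auc, 1 - r$auc)
    # curve starts at (0,0) and ends at (1,1)
    expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
                 c(fpr = 1, tpr = 1))
  }
})

test_that("AUC agrees with the independent pROC implementation", {
  set.seed(15)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.3)
  mine <- rocAuc(scores, labels)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(mine, ref)
})

test_that("single-class labels error", {
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
})

test_that("Kruskal-Wallis statistic matches hand ranking and kruskal.test", {
  out <- groupCompare(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(out$H, 2.4)
  expect_equal(out$pValue, pchisq(2.4, 1, lower.tail = FALSE))

  allTied <- groupCompare(rep(5, 8), rep(c("x", "y"), 4))
  expect_equal(allTied$H, 0)
  expect_equal(allTied$pValue, 1)

  set.seed(16)
  v <- round(rnorm(60), 1)
  g <- sample(c("g1", "g2", "g3"), 60, replace = TRUE)
  mine <- groupCompare(v, g)
  ref <- kruskal.test(v, factor(g))
  expect_equal(mine$H, unname(ref$statistic))
  expect_equal(mine$pValue, ref$p.value)
  expect_equal(mine$H, kwOracle(v, g))
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(17)
  v <- rnorm(40)
  g <- rep(c("a", "b"), 20)
  h0 <- groupCompare(v, g)$H
  expect_equal(groupCompare(exp(v), g)$H, h0)
  expect_equal(groupCompare(v^3, g)$H, h0)
})

test_that("group comparison type-I error is calibrated", {
  set.seed(18)
  rejections <- vapply(1:400, function(i) {
    v <- rnorm(40)
    groupCompare(v, rep(c("a", "b"), 20))$pValue < 0.05
  }, TRUE)
  # binomial 99.9% bounds around 0.05 for 400 trials
  expect_gte(sum(rejections), 5)
  expect_lte(sum(rejections), 38)
})

test_that("Pearson correlation matches the closed form and cor.test", {
  x <- c(-1, 0, 1)
  expect_equal(pearsonCorrelation(x, 2 * x)$r, 1)
  expect_equal(pearsonCorrelation(x, c(1, -2, 1))$r, 0)
  set.seed(19)
  a <- rnorm(10); b <- rnorm(10) + a
  mine <- pearsonCorrelation(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$pValue, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-6)
  expect_error(pearsonCorrelation(c(1, 1, 1), b[1:3]), "constant")
})

test_that("family prevalence applies the minimum-size filter", {
  ids <- c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:19))
  fam <- c(rep("big", 20), rep("small", 19))
  phen <- c(rep(1L, 5), rep(0L, 15), rep(1L, 3), rep(0L, 16))
  ped <- newPedigree(ids, rep(NA, 39), rep(NA, 39), familyId = fam,
                     phenotype = phen)
  fp <- familyPrevalence(ped, minSize = 20)
  expect_equal(fp$families$familyId, "big")
  expect_equal(fp$families$prevalence, 0.25)
  expect_equal(fp$excluded$familyId, "small") # 19 members: excluded
  expect_warning(familyPrevalence(ped, minSize = 50), "below the minimum")
})

test_that("parental-mean EGV prediction accuracy grows with heritability", {
  # accuracy = corr(true offspring breeding value, parental-mean EGV);
  # more heritable traits make parental genetic merit better estimable,
  # so the parental-mean predictor tracks true offspring merit better
  sigmaFor <- c(1 / 9, 3 / 7, 1) # implied h2 0.1, 0.3, 0.5
  meanAcc <- vapply(sigmaFor, function(s2a) {
    mean(vapply(1:5, function(s) {
      cfg <- simulationConfig(nFamilies = 10, seed = 600 + s, sigma2A = s2a)
      sim <- simulatePhenotypes(simulatePedigree(cfg), cfg)
      sys <- buildDesign(sim$ped, modelSpec("III"))
      ps <- runChain(sys, mcmcConfig(4000, 800, 4, seed = 610 + s))
      tab <- egvTable(ps, sim$ped)
      pm <- parentalMeanEGV(tab, sim$ped)
      atrue <- sim$truth$breedingValue[match(tab$id, sim$truth$id)]
      keep <- !is.na(pm)
      cor(atrue[keep], pm[keep])
    }, 0))
  }, 0)
  expect_true(all(meanAcc > 0))
  expect_true(all(diff(meanAcc) > 0))
})

test_that("EGVs track true breeding values and discriminate cases on synthetic data", {
  cfg <- simulationConfig(nFamilies = 12, seed = 23, sigma2A = 0.67) # h2 = 0.4
  sim <- simulatePhenotypes(simulatePedigree(cfg), cfg)
  sys <- buildDesign(sim$ped, modelSpec("III"))
  ps <- runChain(sys, mcmcConfig(6000, 1000, 5, seed = 24))
  tab <- egvTable(ps, sim$ped)
  truth <- sim$truth$breedingValue[match(tab$id, sim$truth$id)]
  expect_gt(cor(tab$egv, truth), 0.3)
  expect_gt(rocAuc(tab$egv, pedResponse(sim$ped))$auc, 0.5)
  # offspring EGV correlates positively with the parental mean
  pm <- parentalMeanEGV(tab, sim$ped)
  keep <- !is.na(pm)
  expect_gt(cor(tab$egv[keep], pm[keep]), 0)
})
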