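# Synthetic pedigrees and phenotypes from the generative model the
# analysis assumes, with known ground truth.
#
# Default settings emulate a familial-cancer registry: ~96 multi-
# generation families (founder couple + 3 descendant generations,
# truncated-Poisson offspring counts, spouses mostly married-in
# founders), binary status from a liability with unit residual variance
# and moderate additive heritability, marginal prevalence ~0.15.

#' Create a simulation configuration
#'
#' @param nFamilies number of independent families.
#' @param generations total generations including the founder couple (>= 2).
#' @param meanChildren mean of the Poisson offspring count per couple.
#' @param mateImmigration probability a spouse is a new unrelated founder
#'   (otherwise an unrelated within-family candidate is sought first).
#' @param sigma2A,sigma2Family,sigma2Generation liability-scale variance
#'   components (additive-genetic, family environment, generation).
#' @param targetPrevalence marginal affected probability the liability
#'   intercept is calibrated to.
#' @param seed RNG seed.
#' @param sexEffect liability shift for males.
#' @return a [SimulationConfig-class]
#' @export
#' @examples
#' simulationConfig(nFamilies = 10) # default sigma2A = 3/7: implied h2 = 0.3
simulationConfig <- function(nFamilies = 96L, generations = 4L,
                             meanChildren = 2.5, mateImmigration = 0.9,
                             sigma2A = 3 / 7, sigma2Family = 0.0,
                             sigma2Generation = 0.0,
                             targetPrevalence = 0.15, seed = 1L,
                             sexEffect = 0) {
  new("SimulationConfig",
      nFamilies = as.integer(nFamilies), generations = as.integer(generations),
      meanChildren = meanChildren, mateImmigration = mateImmigration,
      sigma2A = sigma2A, sigma2Family = sigma2Family,
      sigma2Generation = sigma2Generation,
      targetPrevalence = targetPrevalence, seed = as.integer(seed),
      sexEffect = sexEffect)
}

#' Liability heritability implied by a simulation configuration
#'
#' \code{sigma2A / (sigma2A + sigma2Family + sigma2Generation + 1)} —
#' the residual liability variance is 1 by construction.
#'
#' @param cfg a [SimulationConfig-class]
#' @return numeric in [0, 1)
#' @export
impliedH2 <- function(cfg) {
  tot <- cfg@sigma2A + cfg@sigma2Family + cfg@sigma2Generation + 1
  cfg@sigma2A / tot
}

#' Simulate a multi-family pedigree
#'
#' Each family starts from a founder couple in generation 0. Every couple
#' has a Poisson(\code{meanChildren}) number of children; each child of a
#' non-terminal generation takes a spouse — a newly created founder with
#' probability \code{mateImmigration}, otherwise an unrelated unmarried
#' within-family member of the same generation if one exists (falling
#' back to a new founder) — and the couple continues the family. Sexes
#' within a couple are opposite; child sexes are uniform. Deterministic
#' given the seed.
#'
#' @param cfg a [SimulationConfig-class]
#' @return a [Pedigree-class] (csv dialect, phenotypes all NA until
#'   [simulatePhenotypes()] is applied).
#' @export
simulatePedigree <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed)
  id <- character(); father <- character(); mother <- character()
  sex <- character(); familyId <- character(); generation <- integer()
  ancestors <- list() # founder-ancestor sets, for unrelatedness checks
  counter <- 0L

  addInd <- function(fam, gen, sx, fa = NA_character_, mo = NA_character_) {
    counter <<- counter + 1L
    newId <- sprintf("%s_%04d", fam, counter)
    id <<- c(id, newId); father <<- c(father, fa); mother <<- c(mother, mo)
    sex <<- c(sex, sx); familyId <<- c(familyId, fam)
    generation <<- c(generation, gen)
    ancestors[[newId]] <<- if (is.na(fa)) newId else
      union(ancestors[[fa]], ancestors[[mo]])
    newId
  }

  for (f in seq_len(cfg@nFamilies)) {
    fam <- sprintf("FAM%03d", f)
    counter <- 0L
    pa <- addInd(fam, 0L, "male")
    ma <- addInd(fam, 0L, "female")
    # a couple is (father id, mother id, offspring count); the offspring
    # count is drawn at pairing time so childless pairings never add a
    # disconnected married-in spouse to the pedigree. The founding couple
    # always has at least one child (a registry family exists because it
    # has descendants).
    couples <- list(list(pa, ma, max(1L, stats::rpois(1, cfg@meanChildren))))
    for (g in seq_len(cfg@generations - 1L)) {
      children <- character()
      for (cp in couples) {
        for (k in seq_len(cp[[3]])) {
          sx <- if (stats::runif(1) < 0.5) "male" else "female"
          children <- c(children, addInd(fam, g, sx, cp[[1]], cp[[2]]))
        }
      }
      if (g == cfg@generations - 1L) break
      couples <- list()
      unmarried <- children
      for (child in children) {
        if (!(child %in% unmarried)) next
        nk <- stats::rpois(1, cfg@meanChildren)
        if (nk == 0L) next # no offspring: no spouse enters the pedigree
        unmarried <- setdiff(unmarried, child)
        spouseSex <- if (sex[match(child, id)] == "male") "female" else "male"
        spouse <- NA_character_
        if (stats::runif(1) >= cfg@mateImmigration) {
          cand <- unmarried[sex[match(unmarried, id)] == spouseSex]
          cand <- cand[vapply(cand, function(cc) {
            !length(intersect(ancestors[[cc]], ancestors[[child]]))
          }, TRUE)]
          if (length(cand)) {
            spouse <- cand[1]
            unmarried <- setdiff(unmarried, spouse)
          }
        }
        if (is.na(spouse)) spouse <- addInd(fam, g, spouseSex)
        couples <- c(couples, list(
          if (sex[match(child, id)] == "male") list(child, spouse, nk)
          else list(spouse, child, nk)
        ))
      }
    }
  }
  newPedigree(id = id, father = father, mother = mother, sex = sex,
              familyId = familyId, generation = generation,
              dialect = "csv")
}

#' Simulate liabilities and binary phenotypes on a pedigree
#'
#' Infinitesimal model: founder breeding values are Normal(0, sigma2A);
#' a non-founder's is the parental mean plus a Mendelian-sampling term
#' with variance \code{0.5 * sigma2A * (1 - (F_s + F_d) / 2)} (exact
#' under parental inbreeding). Liability = intercept + sexEffect for
#' males + breeding value + family effect + generation effect + unit
#' Normal residual, with the intercept set to
#' \code{-qnorm(1 - targetPrevalence) * sqrt(total variance)} so the
#' marginal affected probability matches the target. Phenotype = 1 iff
#' liability > 0. The realized (not forced) prevalence is reported.
#'
#' @param ped a [Pedigree-class], typically from [simulatePedigree()].
#' @param cfg the [SimulationConfig-class].
#' @return list: \code{ped} (phenotypes filled in), \code{truth}
#'   data.frame(id, breedingValue, familyEffect, generationEffect,
#'   liability, phenotype), \code{realizedPrevalence}, \code{impliedH2},
#'   \code{mu}.
#' @export
simulatePhenotypes <- function(ped, cfg) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimulationConfig"))
  set.seed(cfg@seed + 1L)
  ord <- sortParentsFirst(ped)
  idx <- match(ord, ped@id)
  fi <- match(ped@father[idx], ord)
  mi <- match(ped@mother[idx], ord)
  Fcoef <- if (cfg@sigma2A > 0) inbreeding(ped)[ped@id[idx]] else numeric(length(ord))
  n <- length(ord)

  a <- numeric(n)
  if (cfg@sigma2A > 0) {
    for (k in seq_len(n)) {
      if (is.na(fi[k]) && is.na(mi[k])) {
        a[k] <- stats::rnorm(1, 0, sqrt(cfg@sigma2A))
      } else {
        pm <- mean(c(if (!is.na(fi[k])) a[fi[k]], if (!is.na(mi[k])) a[mi[k]]))
        Fs <- if (!is.na(fi[k])) Fcoef[fi[k]] else 0
        Fd <- if (!is.na(mi[k])) Fcoef[mi[k]] else 0
        # a missing parent contributes founder-level variance on its side
        nKnown <- sum(!is.na(c(fi[k], mi[k])))
        msVar <- if (nKnown == 2L) 0.5 * cfg@sigma2A * (1 - (Fs + Fd) / 2)
                 else 0.75 * cfg@sigma2A * (1 - Fs / 3 - Fd / 3)
        a[k] <- pm * nKnown / 2 + stats::rnorm(1, 0, sqrt(msVar))
      }
    }
  }

  fams <- factor(ped@familyId[idx])
  famEff <- stats::rnorm(nlevels(fams), 0, sqrt(cfg@sigma2Family))[as.integer(fams)]
  gens <- factor(ped@generation[idx])
  genEff <- stats::rnorm(nlevels(gens), 0, sqrt(cfg@sigma2Generation))[as.integer(gens)]

  totVar <- cfg@sigma2A + cfg@sigma2Family + cfg@sigma2Generation + 1
  mu <- -stats::qnorm(1 - cfg@targetPrevalence) * sqrt(totVar)
  male <- ped@sex[idx] == "male"
  liab <- mu + cfg@sexEffect * male + a + famEff + genEff + stats::rnorm(n)
  phen <- as.integer(liab > 0)

  back <- match(ped@id, ord)
  ped@phenotype <- phen[back]
  ped@cancerType <- ifelse(ped@phenotype == 1L, "cancer", NA_character_)
  truth <- data.frame(
    id = ord, breedingValue = a, familyEffect = famEff,
    generationEffect = genEff, liability = liab, phenotype = phen,
    stringsAsFactors = FALSE
  )[back, ]
  rownames(truth) <- NULL
  list(ped = ped, truth = truth,
       realizedPrevalence = mean(phen), impliedH2 = impliedH2(cfg), mu = mu)
}

#' Simulate-then-refit recovery experiment
#'
#' For each replicate: simulate a pedigree and phenotypes, fit the
#' individual + family + generation threshold model (preset III), and
#' summarize heritability. Reports per-replicate point estimates and HPD
#' intervals plus bias, RMSE and HPD coverage of the true liability
#' heritability. Replicate seeds are derived deterministically from the
#' configuration seed.
#'
#' @param cfg a [SimulationConfig-class] (its seed is the master seed).
#' @param mcmc an [MCMCConfig-class] (its seed is ignored; per-replicate
#'   seeds are derived).
#' @param replicates number of replicates.
#' @param spec model configuration (default preset III).
#' @return data.frame (one row per replicate: seed, h2Hat, hpdLower,
#'   hpdUpper, covered, realizedPrevalence) with attributes
#'   \code{trueH2}, \code{bias}, \code{rmse}, \code{coverage}.
#' @export
recoveryExperiment <- function(cfg, mcmc, replicates = 20,
                               spec = modelSpec("III")) {
  rows <- vector("list", replicates)
  trueH2 <- impliedH2(cfg)
  for (r in seq_len(replicates)) {
    repSeed <- as.integer((as.numeric(cfg@seed) * 1000 + r) %% 2147483647)
    cfgR <- cfg; cfgR@seed <- as.integer(repSeed)
    sim <- simulatePhenotypes(simulatePedigree(cfgR), cfgR)
    sys <- buildDesign(sim$ped, spec)
    mc <- mcmc; mc@seed <- as.integer(repSeed + 7L)
    ps <- runChain(sys, mc)
    est <- heritabilityFromSamples(ps, includeResidual = TRUE,
                                   prevalence = sim$realizedPrevalence)
    rows[[r]] <- data.frame(
      seed = repSeed, h2Hat = est@h2Liability,
      hpdLower = est@hpdLiability[1], hpdUpper = est@hpdLiability[2],
      covered = est@hpdLiability[1] <= trueH2 & trueH2 <= est@hpdLiability[2],
      realizedPrevalence = sim$realizedPrevalence
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "trueH2") <- trueH2
  attr(out, "bias") <- mean(out$h2Hat) - trueH2
  attr(out, "rmse") <- sqrt(mean((out$h2Hat - trueH2)^2))
  attr(out, "coverage") <- mean(out$covered)
  out
}
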