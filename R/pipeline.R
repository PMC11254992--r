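# End-to-end orchestration: read -> validate -> exclude off-kindred ->
# relationship -> fit model(s) -> diagnostics -> heritability table ->
# EGV analyses -> ROC -> family prevalence, with a deterministic,
# logged artifact bundle on disk.

#' Run the full analysis pipeline
#'
#' Fits one or more model presets to a pedigree and writes a bundle of
#' deterministic outputs into \code{outDir}:
#' \describe{
#'   \item{heritability_table.csv}{model x scale x (point, lower, upper)
#'     — the heritability report on both scales.}
#'   \item{egv.csv}{per-individual EGVs with IQR and parental-mean
#'     predictions (last fitted model).}
#'   \item{roc.csv}{ROC curve points for the EGV score and for the
#'     parental-mean score.}
#'   \item{diagnostics.json}{Heidelberger-Welch results per variance
#'     chain and per model, AUCs, group comparison, family-prevalence
#'     correlation, retained draw counts.}
#'   \item{run.log}{input hash, seed, configuration echo, stage trace.}
#' }
#' A convergence-diagnostic failure is reported as a warning in the
#' bundle, not an abort. Rerunning with the same inputs and seed
#' reproduces every numeric output exactly.
#'
#' @param pedigree a [Pedigree-class], or a file path.
#' @param dialect pedigree file dialect when \code{pedigree} is a path.
#' @param models character vector of model presets to fit.
#' @param response "any_cancer" or "pdac".
#' @param preset MCMC preset name (see [mcmcPreset()]).
#' @param seed master seed (per-model chain seeds derived from it).
#' @param outDir output directory (created if needed).
#' @param includeResidual denominator convention for heritability.
#' @param prevalence optional prevalence override for the observed scale.
#' @param excludeOffKindredFirst apply [excludeOffKindred()] (default TRUE).
#' @param strict abort on pedigree validation errors (default TRUE; the
#'   report is always written).
#' @return invisibly, a list with the in-memory results: per-model
#'   heritability estimates, diagnostics, the EGV table, ROC results and
#'   the family-prevalence table.
#' @export
runPipeline <- function(pedigree, dialect = "csv", models = "III",
                        response = c("any_cancer", "pdac"),
                        preset = "desk", seed = 1L, outDir,
                        includeResidual = TRUE, prevalence = NULL,
                        excludeOffKindredFirst = TRUE, strict = TRUE) {
  response <- match.arg(response)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLines <- character()
  logIt <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    writeLines(logLines, logPath)
  }

  stage <- "read"
  result <- tryCatch({
    ped <- if (is(pedigree, "Pedigree")) pedigree else
      readPedigree(pedigree, dialect)
    inputHash <- digestPedigree(ped)
    logIt("pedblup pipeline | seed=", seed, " | preset=", preset,
          " | models=", paste(models, collapse = ","),
          " | response=", response)
    logIt("input: ", nIndividuals(ped), " individuals, hash=", inputHash)

    stage <- "validate"
    report <- validatePedigree(ped)
    jsonlite::write_json(
      list(errors = validationErrors(report),
           warnings = validationWarnings(report)),
      file.path(outDir, "validation.json")
    )
    if (!validationPassed(report)) {
      if (strict) stop("pedigree validation failed (see validation.json)")
      logIt("WARNING: pedigree validation reported errors")
    }

    stage <- "exclude_off_kindred"
    if (excludeOffKindredFirst) {
      ped <- excludeOffKindred(ped)
      logIt("off-kindred exclusion dropped ", attr(ped, "dropped"),
            " individual(s); ", nIndividuals(ped), " remain")
    }

    prev <- if (is.null(prevalence)) {
      y <- responseVector(ped, response)
      mean(y)
    } else prevalence
    logIt("prevalence used for observed scale: ", format(prev, digits = 4))

    heritRows <- list(); diagList <- list(); estList <- list()
    psLast <- NULL
    for (mi in seq_along(models)) {
      m <- models[mi]
      stage <- paste0("fit_model_", m)
      spec <- modelSpec(m, response = response)
      sys <- buildDesign(ped, spec)
      cfg <- mcmcPreset(preset, seed = as.integer(seed) + 101L * mi)
      ps <- runChain(sys, cfg)
      psLast <- ps
      logIt("model ", m, ": ", nrow(varianceDraws(ps)), " retained draws")

      stage <- paste0("diagnostics_model_", m)
      vd <- varianceDraws(ps)
      dg <- lapply(setdiff(colnames(vd), "residual"), function(cn) {
        d <- heidelbergerWelch(vd[, cn])
        if (!d@stationarityPassed) {
          logIt("WARNING: model ", m, " variance chain '", cn,
                "' failed the stationarity test")
        }
        list(component = cn, stationarityPassed = d@stationarityPassed,
             fractionDiscarded = d@fractionDiscarded,
             halfwidthPassed = d@halfwidthPassed,
             halfwidthRatio = d@halfwidthRatio, pValue = d@pValue)
      })

      stage <- paste0("heritability_model_", m)
      est <- heritabilityFromSamples(ps, includeResidual = includeResidual,
                                     prevalence = prev)
      estList[[m]] <- est
      diagList[[m]] <- dg
      heritRows[[m]] <- data.frame(
        model = m,
        h2_liability = est@h2Liability,
        liability_lower = est@hpdLiability[1],
        liability_upper = est@hpdLiability[2],
        h2_observed = est@h2Observed,
        observed_lower = est@hpdObserved[1],
        observed_upper = est@hpdObserved[2],
        prevalence = prev, n_draws = est@nDraws
      )
    }
    heritTab <- do.call(rbind, heritRows)
    utils::write.csv(heritTab, file.path(outDir, "heritability_table.csv"),
                     row.names = FALSE)

    stage <- "egv"
    tab <- egvTable(psLast, ped)
    tab$parentalMean <- parentalMeanEGV(tab, ped)
    utils::write.csv(tab, file.path(outDir, "egv.csv"), row.names = FALSE)

    stage <- "roc"
    y <- responseVector(ped, response)
    rocEgv <- rocAuc(tab$egv, y)
    rocCurve <- cbind(score = "egv", rocEgv$curve)
    rocPm <- NULL
    if (sum(!is.na(tab$parentalMean) & y == 1) > 0 &&
        sum(!is.na(tab$parentalMean) & y == 0) > 0) {
      rocPm <- rocAuc(tab$parentalMean, y)
      rocCurve <- rbind(rocCurve, cbind(score = "parental_mean", rocPm$curve))
    }
    utils::write.csv(rocCurve, file.path(outDir, "roc.csv"), row.names = FALSE)

    stage <- "group_compare"
    gc <- groupCompare(tab$egv, ifelse(y == 1, "affected", "unaffected"))

    stage <- "family_prevalence"
    fp <- familyPrevalence(ped, tab)

    stage <- "report"
    diagOut <- list(
      models = diagList,
      retained = lapply(estList, function(e) e@nDraws),
      auc_egv = rocEgv$auc,
      auc_parental_mean = if (is.null(rocPm)) NA else rocPm$auc,
      kruskal_wallis = list(H = gc$H, df = gc$df, pValue = gc$pValue),
      family_prevalence_correlation =
        if (is.null(fp$correlation)) NULL else fp$correlation
    )
    jsonlite::write_json(diagOut, file.path(outDir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(fp$families, file.path(outDir, "family_prevalence.csv"),
                     row.names = FALSE)
    logIt("pipeline complete")
    list(heritability = estList, heritabilityTable = heritTab,
         diagnostics = diagList, egv = tab, rocEgv = rocEgv, rocPm = rocPm,
         groupCompare = gc, familyPrevalence = fp, posterior = psLast)
  }, error = function(e) {
    logIt("ERROR at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Run the pipeline from a YAML configuration file
#'
#' The file may set any of: \code{pedigree} (path), \code{dialect},
#' \code{models}, \code{response}, \code{preset}, \code{seed},
#' \code{out_dir}, \code{include_residual}, \code{prevalence},
#' \code{strict}. Arguments in \code{...} override the file.
#'
#' @param path YAML configuration file.
#' @param ... overrides passed to [runPipeline()].
#' @return see [runPipeline()].
#' @export
runPipelineFromConfig <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  args <- list(
    pedigree = cfg$pedigree, dialect = cfg$dialect %||% "csv",
    models = cfg$models %||% "III",
    response = cfg$response %||% "any_cancer",
    preset = cfg$preset %||% "desk", seed = cfg$seed %||% 1L,
    outDir = cfg$out_dir,
    includeResidual = cfg$include_residual %||% TRUE,
    prevalence = cfg$prevalence,
    strict = cfg$strict %||% TRUE
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(runPipeline, args)
}

# small deterministic content hash of the retained pedigree fields
digestPedigree <- function(ped) {
  s <- paste(ped@familyId, ped@id, ped@father, ped@mother, ped@sex,
             ped@generation, ped@phenotype, collapse = ";")
  raw <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(raw, ceiling(seq_along(raw) / 4096))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
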