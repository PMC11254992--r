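# Accessors and show methods for the core classes.

#' Number of individuals in a pedigree
#' @param ped a [Pedigree-class]
#' @return integer
#' @export
nIndividuals <- function(ped) length(ped@id)

#' Individual identifiers
#' @param ped a [Pedigree-class]
#' @return character vector
#' @export
pedIds <- function(ped) ped@id

#' Parse-stage findings attached by [readPedigree()]
#' @param ped a [Pedigree-class]
#' @return list with elements \code{errors} and \code{counts}
#' @export
readReport <- function(ped) ped@readReport

#' Pedigree as a data frame
#'
#' One row per individual with columns \code{family_id, id, father_id,
#' mother_id, sex, generation, phenotype, cancer_type} (the csv dialect
#' layout).
#' @param ped a [Pedigree-class]
#' @return data.frame
#' @export
pedToDataFrame <- function(ped) {
  data.frame(
    family_id = ped@familyId, id = ped@id,
    father_id = ped@father, mother_id = ped@mother,
    sex = ped@sex, generation = ped@generation,
    phenotype = ped@phenotype, cancer_type = ped@cancerType,
    stringsAsFactors = FALSE
  )
}

#' Does a validation report pass?
#' @param report a [ValidationReport-class]
#' @return TRUE iff no errors were recorded
#' @export
validationPassed <- function(report) nrow(report@errors) == 0L

#' Validation errors / warnings tables
#' @param report a [ValidationReport-class]
#' @return data.frame(rule, id, message)
#' @export
validationErrors <- function(report) report@errors

#' @rdname validationErrors
#' @export
validationWarnings <- function(report) report@warnings

#' Additive relationship matrix, inbreeding coefficients and ordering
#' @param rel a [RelationshipMatrix-class]
#' @return matrix / numeric vector / character vector
#' @export
relA <- function(rel) rel@A

#' @rdname relA
#' @export
inbreedingF <- function(rel) rel@F

#' @rdname relA
#' @export
relIds <- function(rel) rel@ids

#' Kinship matrix (half the additive relationship matrix)
#' @param rel a [RelationshipMatrix-class]
#' @return symmetric matrix of kinship coefficients
#' @export
kinshipMatrix <- function(rel) rel@A / 2

#' Components of a mixed-model solution
#' @param sol an [MMESolution-class]
#' @return named numeric vector / list of named numeric vectors
#' @export
fixedEstimates <- function(sol) sol@beta

#' @rdname fixedEstimates
#' @export
randomPredictions <- function(sol) sol@u

#' Posterior draw tables
#' @param ps a [PosteriorSamples-class]
#' @return numeric matrix (draw x column)
#' @export
varianceDraws <- function(ps) ps@varianceDraws

#' @rdname varianceDraws
#' @export
effectDraws <- function(ps) ps@effectDraws

#' @rdname varianceDraws
#' @export
liabilityDraws <- function(ps) ps@liabilityDraws

#' @rdname varianceDraws
#' @export
posteriorMeta <- function(ps) ps@meta

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@father) & is.na(object@mother))
  cat("Pedigree:", n, "individuals,", length(unique(object@familyId)),
      "families (", founders, "founders )\n")
  cat("  affected:", sum(object@phenotype == 1L, na.rm = TRUE),
      " unaffected:", sum(object@phenotype == 0L, na.rm = TRUE),
      " unknown:", sum(is.na(object@phenotype)), "\n")
  cat("  dialect:", object@dialect, "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", nrow(object@errors), "error(s),",
      nrow(object@warnings), "warning(s)\n")
  cat("  read:", object@counts[["read"]], " kept:", object@counts[["kept"]],
      " dropped:", object@counts[["dropped"]], "\n")
  if (nrow(object@errors)) print(utils::head(object@errors, 5))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix:", length(object@ids), "individuals; max F =",
      format(max(object@F), digits = 3), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec (preset ", object@preset, "): fixed [",
      paste(object@fixedEffects, collapse = " + "), "] random [",
      paste(object@randomEffects, collapse = " + "), "] response ",
      object@response, "\n", sep = "")
})

setMethod("show", "MMESystem", function(object) {
  cat("MMESystem:", length(object@y), "records; X:", ncol(object@X),
      "column(s); random blocks:",
      paste(sprintf("%s(%d)", names(object@Zlist),
                    vapply(object@Zlist, ncol, 0L)), collapse = ", "), "\n")
})

setMethod("show", "MCMCConfig", function(object) {
  cat(sprintf(
    "MCMCConfig: %d iterations, burn-in %d, thin %d -> %d retained (%s mode)\n",
    object@nIterations, object@burnIn, object@thin,
    retainedSampleCount(object), object@responseMode
  ))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@varianceDraws), "retained draws;",
      "variance components:", paste(colnames(object@varianceDraws), collapse = ", "), "\n")
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf(
    "Heritability: liability %.2f [%.2f-%.2f]; observed %.2f [%.2f-%.2f] (prevalence %.3f)\n",
    object@h2Liability, object@hpdLiability[1], object@hpdLiability[2],
    object@h2Observed, object@hpdObserved[1], object@hpdObserved[2],
    object@prevalenceUsed
  ))
})

setMethod("show", "DiagnosticResult", function(object) {
  cat(sprintf(
    "Heidelberger-Welch: stationarity %s (discarded %.0f%%, p = %.3f); halfwidth %s (ratio %.3g)\n",
    if (object@stationarityPassed) "passed" else "FAILED",
    100 * object@fractionDiscarded, object@pValue,
    if (is.na(object@halfwidthPassed)) "n/a" else if (object@halfwidthPassed) "passed" else "FAILED",
    object@halfwidthRatio
  ))
})
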