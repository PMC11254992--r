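#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix sparseMatrix crossprod t Diagonal Cholesky solve forceSymmetric drop0
#' @importFrom stats qnorm dnorm pnorm rnorm rpois runif var median quantile sd ar cor pchisq pt complete.cases setNames aggregate
#' @importFrom utils read.table write.csv head
#' @useDynLib pedblup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SEX_LEVELS <- c("female", "male", "unknown")

#' Pedigree of individuals with parent links and binary disease status
#'
#' Central input container: one record per individual with father/mother
#' references (\code{NA} = unknown parent), sex, family membership,
#' generation index and binary phenotype (1 = affected, 0 = unaffected,
#' \code{NA} = unknown). Construct with [newPedigree()] or [readPedigree()].
#'
#' Structural soundness (uniqueness of ids, resolvable parents, acyclicity)
#' is deliberately *not* enforced at construction so that raw, possibly messy
#' registry data can be represented and then audited with
#' [validatePedigree()].
#'
#' @slot id character, unique individual identifiers.
#' @slot father,mother character, parent ids or \code{NA}.
#' @slot sex character, one of \code{"female"}, \code{"male"}, \code{"unknown"}.
#' @slot familyId character, family/kindred identifier.
#' @slot generation integer generation index (founders 0), \code{NA} if unknown.
#' @slot phenotype integer, 1 affected / 0 unaffected / \code{NA} unknown.
#' @slot cancerType character cancer-type label or \code{NA}.
#' @slot dialect character, source-format tag.
#' @slot readReport list, parse-stage findings from [readPedigree()].
#' @aliases Pedigree
#' @exportClass Pedigree
setClass("Pedigree",
  representation(
    id = "character", father = "character", mother = "character",
    sex = "character", familyId = "character", generation = "integer",
    phenotype = "integer", cancerType = "character",
    dialect = "character", readReport = "list"
  ),
  prototype(dialect = "csv", readReport = list())
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  lens <- c(
    length(object@father), length(object@mother), length(object@sex),
    length(object@familyId), length(object@generation),
    length(object@phenotype), length(object@cancerType)
  )
  msgs <- character()
  if (any(lens != n)) msgs <- c(msgs, "all per-individual slots must share one length")
  if (any(is.na(object@id)) || any(object@id == "")) {
    msgs <- c(msgs, "individual ids must be non-missing, non-empty")
  }
  if (!all(object@sex %in% SEX_LEVELS)) {
    msgs <- c(msgs, "sex must be 'female', 'male' or 'unknown'")
  }
  if (!all(object@phenotype %in% c(0L, 1L, NA_integer_))) {
    msgs <- c(msgs, "phenotype must be 0, 1 or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Findings from pedigree validation
#'
#' Errors and warnings collected by [validatePedigree()] (and the parse
#' stage of [readPedigree()]), each a data frame with columns
#' \code{rule}, \code{id}, \code{message}. A pedigree passes iff
#' \code{errors} is empty.
#'
#' @slot errors,warnings data.frame(rule, id, message).
#' @slot counts named integer: individuals \code{read}, \code{kept}, \code{dropped}.
#' @aliases ValidationReport
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(errors = "data.frame", warnings = "data.frame", counts = "integer"),
  prototype(
    errors = data.frame(rule = character(), id = character(), message = character()),
    warnings = data.frame(rule = character(), id = character(), message = character()),
    counts = c(read = 0L, kept = 0L, dropped = 0L)
  )
)

#' Additive (numerator) relationship matrix
#'
#' The expected additive-genetic covariance structure implied by a pedigree:
#' \eqn{A_{ij}} is twice the kinship coefficient, with diagonal
#' \eqn{1 + F_i} where \eqn{F_i} is the inbreeding coefficient. Ids are
#' stored in a parents-first ordering.
#'
#' @slot ids character, parents-first ordering of individuals.
#' @slot A symmetric numeric matrix of additive relationships.
#' @slot F numeric, per-individual inbreeding coefficients (\code{A_ii - 1}).
#' @aliases RelationshipMatrix
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(ids = "character", A = "matrix", F = "numeric")
)

setValidity("RelationshipMatrix", function(object) {
  n <- length(object@ids)
  if (!all(dim(object@A) == n)) return("A must be n x n")
  if (length(object@F) != n) return("F must have one entry per individual")
  if (any(diag(object@A) < 1 - 1e-8)) return("diagonal entries must be >= 1")
  if (max(abs(object@A - t(object@A))) > 1e-10) return("A must be symmetric")
  TRUE
})

#' Mixed-model configuration (fixed and random effect structure)
#'
#' Which factors enter Henderson's equations as fixed effects and which as
#' random effects, plus the modeled binary response. The individual
#' (additive-genetic, "animal") effect is always random. Three standard
#' presets are available through [modelSpec()]: \describe{
#'   \item{I}{fixed sex + family + generation; random individual}
#'   \item{II}{fixed sex + generation; random individual + family}
#'   \item{III}{fixed sex; random individual + family + generation}
#' }
#'
#' @slot fixedEffects character subset of intercept/sex/family/generation.
#' @slot randomEffects character subset of individual/family/generation.
#' @slot response \code{"any_cancer"} or \code{"pdac"}.
#' @slot preset the preset label ("I","II","III" or "custom").
#' @aliases ModelSpec
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    fixedEffects = "character", randomEffects = "character",
    response = "character", preset = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!"individual" %in% object@randomEffects) {
    msgs <- c(msgs, "'individual' must be a random effect")
  }
  if (!all(object@fixedEffects %in% c("intercept", "sex", "family", "generation"))) {
    msgs <- c(msgs, "unknown fixed effect")
  }
  if (!all(object@randomEffects %in% c("individual", "family", "generation"))) {
    msgs <- c(msgs, "unknown random effect")
  }
  dup <- intersect(object@fixedEffects, object@randomEffects)
  if (length(dup)) msgs <- c(msgs, paste0("effect both fixed and random: ", dup[1]))
  if (!object@response %in% c("any_cancer", "pdac")) {
    msgs <- c(msgs, "response must be 'any_cancer' or 'pdac'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Henderson mixed-model equation system
#'
#' Design matrices and covariance structure of the mixed model
#' \eqn{y = X\beta + \sum_b Z_b u_b + e}: the response (observed trait or
#' latent liability), the fixed-effect design \code{X} (reference-level
#' coded, full column rank), one 0/1 incidence matrix per random effect,
#' and the sparse inverse relationship matrix for the individual block.
#'
#' @slot y numeric response (NA allowed for unknown-status liabilities).
#' @slot X dense fixed-effect design matrix.
#' @slot Zlist named list of sparse incidence matrices, one per random block.
#' @slot Ainv sparse inverse additive-relationship matrix (individual block).
#' @slot Rscale residual variance (fixed at 1 for the threshold model).
#' @slot ids row-wise individual ids.
#' @slot spec the originating [ModelSpec-class].
#' @aliases MMESystem
#' @exportClass MMESystem
setClass("MMESystem",
  representation(
    y = "numeric", X = "matrix", Zlist = "list", Ainv = "Matrix",
    Rscale = "numeric", ids = "character", spec = "ModelSpec"
  )
)

setValidity("MMESystem", function(object) {
  n <- length(object@y)
  if (nrow(object@X) != n) return("X row count must match y")
  for (Z in object@Zlist) if (nrow(Z) != n) return("Z row count must match y")
  if (object@Rscale <= 0) return("Rscale must be positive")
  TRUE
})

#' Solution of Henderson's mixed-model equations
#'
#' Fixed-effect estimates \eqn{\hat\beta} and BLUP random-effect
#' predictions \eqn{\hat u}, keyed by effect block and level.
#'
#' @slot beta named numeric, fixed-effect estimates.
#' @slot u named list of named numeric vectors, one per random block.
#' @aliases MMESolution
#' @exportClass MMESolution
setClass("MMESolution", representation(beta = "numeric", u = "list"))

#' MCMC settings for the threshold-model Gibbs sampler
#'
#' Chain length, burn-in, thinning, seed, per-random-effect prior
#' (inverse-gamma scale \code{V}, degree of belief \code{nu}, optional
#' parameter expansion with working-scale prior variance \code{alphaV}),
#' and the response mode (\code{"threshold"} for binary traits with latent
#' liabilities, \code{"gaussian"} for a continuous response used by the
#' conjugate oracle tests). Build with [mcmcConfig()] or [mcmcPreset()].
#'
#' @slot nIterations,burnIn,thin,seed integers.
#' @slot priorV,priorNu,alphaV numerics (scalar, recycled across blocks).
#' @slot parameterExpansion logical.
#' @slot responseMode \code{"threshold"} or \code{"gaussian"}.
#' @slot fixVariances logical; if TRUE variance components are held at their
#'   initial values (conjugate-oracle testing back-door).
#' @slot recordLiabilities logical.
#' @aliases MCMCConfig
#' @exportClass MCMCConfig
setClass("MCMCConfig",
  representation(
    nIterations = "integer", burnIn = "integer", thin = "integer",
    seed = "integer", priorV = "numeric", priorNu = "numeric",
    alphaV = "numeric", parameterExpansion = "logical",
    responseMode = "character", fixVariances = "logical",
    recordLiabilities = "logical"
  )
)

setValidity("MCMCConfig", function(object) {
  msgs <- character()
  if (object@nIterations <= 0L) msgs <- c(msgs, "nIterations must be positive")
  if (object@burnIn < 0L) msgs <- c(msgs, "burnIn must be non-negative")
  if (object@burnIn >= object@nIterations) {
    msgs <- c(msgs, "burnIn must be smaller than nIterations")
  }
  if (object@thin <= 0L) msgs <- c(msgs, "thin must be positive")
  if (!object@responseMode %in% c("threshold", "gaussian")) {
    msgs <- c(msgs, "responseMode must be 'threshold' or 'gaussian'")
  }
  if (object@priorV <= 0 || object@priorNu <= 0 || object@alphaV <= 0) {
    msgs <- c(msgs, "prior hyperparameters must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Thinned posterior draws from the Gibbs sampler
#'
#' Retained post-burn-in draws: variance components per random block (plus
#' the fixed residual scale), fixed effects and individual genetic effects,
#' and optionally latent liabilities. Row count equals
#' [retainedSampleCount()] of the configuration.
#'
#' @slot varianceDraws numeric matrix, draw x component.
#' @slot effectDraws numeric matrix, draw x effect-level (beta then u blocks).
#' @slot liabilityDraws numeric matrix (0 rows when not recorded).
#' @slot effectBlocks integer index (0 fixed, then 1..B) per effectDraws column.
#' @slot meta list: config echo, model spec echo, ids, block names.
#' @aliases PosteriorSamples
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(
    varianceDraws = "matrix", effectDraws = "matrix",
    liabilityDraws = "matrix", effectBlocks = "integer", meta = "list"
  )
)

#' Heritability estimate on the liability and observed scales
#'
#' Posterior-mean narrow-sense heritability with highest-posterior-density
#' intervals, on the latent liability scale and after threshold-model
#' (Dempster-Lerner) conversion to the observed (0/1 "real") scale at a
#' given prevalence.
#'
#' @slot h2Liability,h2Observed numeric point estimates in [0, 1].
#' @slot hpdLiability,hpdObserved numeric length-2 (lower, upper).
#' @slot prevalenceUsed numeric in (0, 1).
#' @slot includeResidual logical: residual liability variance in denominator.
#' @slot nDraws integer.
#' @aliases HeritabilityEstimate
#' @exportClass HeritabilityEstimate
setClass("HeritabilityEstimate",
  representation(
    h2Liability = "numeric", hpdLiability = "numeric",
    h2Observed = "numeric", hpdObserved = "numeric",
    prevalenceUsed = "numeric", includeResidual = "logical",
    nDraws = "integer"
  )
)

#' Heidelberger-Welch convergence diagnostic result
#'
#' @slot stationarityPassed logical.
#' @slot fractionDiscarded numeric in {0, 0.1, ..., 0.5}.
#' @slot halfwidthPassed logical (NA when not applicable).
#' @slot halfwidthRatio numeric (NA when not applicable).
#' @slot pValue numeric, Cramer-von-Mises p at the accepted start point.
#' @aliases DiagnosticResult
#' @exportClass DiagnosticResult
setClass("DiagnosticResult",
  representation(
    stationarityPassed = "logical", fractionDiscarded = "numeric",
    halfwidthPassed = "logical", halfwidthRatio = "numeric",
    pValue = "numeric"
  )
)

#' Synthetic pedigree/phenotype generator settings
#'
#' Ground-truth generative model: family and pedigree structure (founder
#' couples, truncated-Poisson offspring counts, spouse immigration) and the
#' liability model (additive-genetic, family and generation variance
#' components on top of a unit residual), thresholded at 0 after centering
#' the liability so the marginal affected probability matches
#' \code{targetPrevalence}. Build with [simulationConfig()].
#'
#' @slot nFamilies,generations,seed integers.
#' @slot meanChildren,mateImmigration numerics.
#' @slot sigma2A,sigma2Family,sigma2Generation numerics (liability scale).
#' @slot targetPrevalence numeric in (0, 1).
#' @slot sexEffect numeric liability shift for males.
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nFamilies = "integer", generations = "integer", meanChildren = "numeric",
    mateImmigration = "numeric", sigma2A = "numeric", sigma2Family = "numeric",
    sigma2Generation = "numeric", targetPrevalence = "numeric",
    seed = "integer", sexEffect = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@generations < 2L) msgs <- c(msgs, "generations must be >= 2")
  if (object@meanChildren <= 0) msgs <- c(msgs, "meanChildren must be positive")
  if (object@mateImmigration < 0 || object@mateImmigration > 1) {
    msgs <- c(msgs, "mateImmigration must be a probability")
  }
  if (min(object@sigma2A, object@sigma2Family, object@sigma2Generation) < 0) {
    msgs <- c(msgs, "variances must be >= 0")
  }
  if (object@targetPrevalence <= 0 || object@targetPrevalence >= 1) {
    msgs <- c(msgs, "targetPrevalence must be in (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})
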