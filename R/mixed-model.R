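# Model configurations and Henderson's mixed-model equations.

#' Create a mixed-model configuration
#'
#' Either pick one of the three standard presets or give explicit effect
#' lists. The intercept is always included among the fixed effects (the
#' threshold is fixed at 0, so the intercept carries prevalence).
#'
#' @param preset "I", "II", "III" or NULL for a custom specification.
#' @param fixedEffects,randomEffects character vectors (custom only).
#' @param response "any_cancer" (default) or "pdac".
#' @return a [ModelSpec-class]
#' @export
#' @examples
#' modelSpec("III")
#' modelSpec(fixedEffects = "sex", randomEffects = c("individual", "family"))
modelSpec <- function(preset = NULL, fixedEffects = NULL, randomEffects = NULL,
                      response = c("any_cancer", "pdac")) {
  response <- match.arg(response)
  if (!is.null(preset)) {
    preset <- match.arg(as.character(preset), c("I", "II", "III"))
    fixedEffects <- switch(preset,
      I = c("sex", "family", "generation"),
      II = c("sex", "generation"),
      III = "sex"
    )
    randomEffects <- switch(preset,
      I = "individual",
      II = c("individual", "family"),
      III = c("individual", "family", "generation")
    )
  } else {
    preset <- "custom"
    if (is.null(randomEffects)) randomEffects <- "individual"
    if (is.null(fixedEffects)) fixedEffects <- character()
  }
  new("ModelSpec",
      fixedEffects = unique(c("intercept", fixedEffects)),
      randomEffects = randomEffects, response = response, preset = preset)
}

responseVector <- function(ped, response, unknownAsMissing = FALSE) {
  y <- switch(response,
    any_cancer = ped@phenotype,
    pdac = {
      p <- ifelse(!is.na(ped@cancerType) & ped@cancerType == "PDAC", 1L, 0L)
      p[is.na(ped@phenotype) & is.na(ped@cancerType)] <- NA_integer_
      p
    }
  )
  if (!unknownAsMissing) y[is.na(y)] <- 0L
  as.numeric(y)
}

incidenceMatrix <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f)),
    dimnames = list(NULL, levels(f))
  )
}

#' Build Henderson's equations for a pedigree and model configuration
#'
#' Assembles the response, the reference-level-coded fixed-effect design
#' (intercept always present; sex reference level female; fixed family /
#' generation as dummies against their first level), one 0/1 incidence
#' matrix per random effect — the individual block ordered parents-first
#' to match [aInverse()] — and the sparse inverse relationship matrix.
#' Fixed factors with a single observed level are dropped with a warning.
#'
#' @param ped a validated [Pedigree-class].
#' @param spec a [ModelSpec-class].
#' @param unknownAsMissing keep unknown phenotypes as NA (their liabilities
#'   are then sampled unconstrained by [runChain()]) instead of coding them
#'   unaffected.
#' @return an [MMESystem-class]
#' @export
buildDesign <- function(ped, spec, unknownAsMissing = FALSE) {
  stopifnot(is(spec, "ModelSpec"))
  y <- responseVector(ped, spec@response, unknownAsMissing)
  n <- length(y)

  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  addFixedFactor <- function(X, values, prefix) {
    f <- factor(values)
    if (nlevels(f) < 2L) {
      warning("fixed effect '", prefix, "' has a single level; dropped")
      return(X)
    }
    dum <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(dum) <- paste0(prefix, "_", levels(f)[-1])
    cbind(X, dum)
  }
  if ("sex" %in% spec@fixedEffects) {
    sex <- factor(ped@sex, levels = c("female", "male", "unknown"))
    sex <- droplevels(sex)
    if (nlevels(sex) < 2L) {
      warning("fixed effect 'sex' has a single level; dropped")
    } else {
      dum <- stats::model.matrix(~sex)[, -1, drop = FALSE]
      colnames(dum) <- paste0("sex_", levels(sex)[-1])
      X <- cbind(X, dum)
    }
  }
  if ("family" %in% spec@fixedEffects) X <- addFixedFactor(X, ped@familyId, "family")
  if ("generation" %in% spec@fixedEffects) X <- addFixedFactor(X, ped@generation, "generation")

  ord <- sortParentsFirst(ped)
  Zlist <- list()
  for (eff in spec@randomEffects) {
    Zlist[[eff]] <- switch(eff,
      individual = Matrix::sparseMatrix(
        i = seq_len(n), j = match(ped@id, ord), x = 1, dims = c(n, n),
        dimnames = list(NULL, ord)
      ),
      family = incidenceMatrix(ped@familyId),
      generation = incidenceMatrix(ped@generation)
    )
  }

  new("MMESystem",
      y = y, X = X, Zlist = Zlist, Ainv = aInverse(ped),
      Rscale = 1, ids = ped@id, spec = spec)
}

#' Solve Henderson's mixed-model equations
#'
#' For given variance components, solves the symmetric system
#' \deqn{\begin{bmatrix} X'R^{-1}X & X'R^{-1}Z \\ Z'R^{-1}X & Z'R^{-1}Z + G^{-1}\end{bmatrix}
#'       \begin{bmatrix}\hat\beta\\ \hat u\end{bmatrix} =
#'       \begin{bmatrix} X'R^{-1}y \\ Z'R^{-1}y \end{bmatrix}}
#' where \eqn{G^{-1}} is block diagonal: \eqn{A^{-1}/\sigma^2_a} for the
#' individual block and \eqn{I/\sigma^2_b} for family/generation blocks.
#'
#' @param sys an [MMESystem-class] (NA responses are not allowed here).
#' @param vc named numeric variance components: one entry per random block
#'   (\code{individual}, \code{family}, \code{generation} as present) and
#'   optionally \code{residual} (defaults to \code{Rscale} of the system).
#' @return an [MMESolution-class]
#' @export
#' @examples
#' ped <- newPedigree(c("s", "d", "c"), c(NA, NA, "s"), c(NA, NA, "d"),
#'                    phenotype = c(0, 1, 1))
#' sys <- buildDesign(ped, modelSpec(fixedEffects = character()))
#' solveMME(sys, c(individual = 0.5))
solveMME <- function(sys, vc) {
  stopifnot(is(sys, "MMESystem"))
  if (anyNA(sys@y)) stop("response contains NA; solveMME needs complete records")
  blocks <- names(sys@Zlist)
  missingVc <- setdiff(blocks, names(vc))
  if (length(missingVc)) stop("missing variance component(s): ", paste(missingVc, collapse = ", "))
  if (any(vc[blocks] <= 0)) stop("variance components must be > 0")
  Rscale <- if ("residual" %in% names(vc)) vc[["residual"]] else sys@Rscale

  W <- Matrix::Matrix(sys@X, sparse = TRUE)
  if (length(sys@Zlist)) W <- cbind(W, do.call(cbind, unname(sys@Zlist)))
  C <- Matrix::crossprod(W) / Rscale
  rhs <- Matrix::crossprod(W, sys@y) / Rscale

  p <- ncol(sys@X)
  off <- p
  C <- as(C, "CsparseMatrix")
  for (b in blocks) {
    q <- ncol(sys@Zlist[[b]])
    idx <- off + seq_len(q)
    Gi <- if (b == "individual") sys@Ainv / vc[[b]] else Matrix::Diagonal(q) / vc[[b]]
    C[idx, idx] <- C[idx, idx] + Gi
    off <- off + q
  }
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(C), rhs)),
    error = function(e) stop("singular mixed-model equations (",
                             conditionMessage(e), ")")
  )
  beta <- setNames(sol[seq_len(p)], colnames(sys@X))
  u <- list(); off <- p
  for (b in blocks) {
    q <- ncol(sys@Zlist[[b]])
    u[[b]] <- setNames(sol[off + seq_len(q)], colnames(sys@Zlist[[b]]))
    off <- off + q
  }
  new("MMESolution", beta = beta, u = u)
}
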