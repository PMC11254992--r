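# Gibbs sampler front end.

#' One-sided truncated normal draws
#'
#' Draws from Normal(mean, sd^2) restricted to the positive half-line
#' (\code{side = "above_0"}, used for affected individuals' liabilities)
#' or the non-positive half-line (\code{side = "below_0"}). Uses plain
#' rejection near the bulk and Robert's exponential rejection in the far
#' tail, so draws remain exact and O(1) even for |mean|/sd up to 30.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param side "above_0" or "below_0".
#' @return numeric vector of n draws.
#' @export
#' @examples
#' set.seed(1)
#' mean(sampleTruncatedNormal(1e4, 0, 1, "above_0")) # ~ sqrt(2/pi)
sampleTruncatedNormal <- function(n, mean = 0, sd = 1,
                                  side = c("above_0", "below_0")) {
  side <- match.arg(side)
  stopifnot(sd > 0)
  .rtruncnormCpp(as.integer(n), mean, sd, side == "above_0")
}

# align a P x P sparse component onto the combined CSC pattern (cp, ci):
# returns values vector over the pattern's nnz entries.
alignToPattern <- function(cp, ci, S) {
  S <- as(as(S, "generalMatrix"), "CsparseMatrix")
  out <- numeric(length(ci))
  sp <- S@p; si <- S@i; sx <- S@x
  for (j in seq_len(length(cp) - 1L)) {
    sk <- (sp[j] + 1L):sp[j + 1L]
    if (sp[j + 1L] == sp[j]) next
    pk <- (cp[j] + 1L):cp[j + 1L]
    pos <- match(si[sk], ci[pk])
    out[pk[pos]] <- sx[sk]
  }
  out
}

#' Run the threshold-model Gibbs chain
#'
#' Data-augmentation Gibbs sampler for the liability-threshold animal
#' model. Each iteration (threshold mode): (1) latent liabilities are
#' redrawn from one-sided truncated normals around the current linear
#' predictor (unconstrained for unknown phenotypes); (2) all location
#' effects (fixed effects and every random block) are updated by a
#' single-site sweep over Henderson's equations at the current variance
#' components; (3) each random-effect variance is drawn from its
#' scaled-inverse-chi-square full conditional, with MCMCglmm-style
#' parameter expansion when enabled. The residual liability variance
#' stays fixed (identification). Gaussian mode skips step (1) and treats
#' the response as the observed trait — a conjugate setting used by the
#' oracle tests.
#'
#' Fully reproducible: the chain is a deterministic function of the
#' configuration's seed.
#'
#' @param sys an [MMESystem-class] from [buildDesign()].
#' @param cfg an [MCMCConfig-class].
#' @param yGauss optional numeric response overriding \code{sys@y} in
#'   gaussian mode.
#' @param sigma2Init optional named initial variances per random block.
#' @return a [PosteriorSamples-class]
#' @export
runChain <- function(sys, cfg, yGauss = NULL, sigma2Init = NULL) {
  stopifnot(is(sys, "MMESystem"), is(cfg, "MCMCConfig"))
  nret <- retainedSampleCount(cfg)
  threshold <- cfg@responseMode == "threshold"
  if (threshold && !all(sys@y %in% c(0, 1, NA))) {
    stop("threshold mode requires a binary (0/1/NA) response")
  }

  blocks <- names(sys@Zlist)
  B <- length(blocks)
  W <- Matrix::Matrix(sys@X, sparse = TRUE)
  if (B) W <- cbind(W, do.call(cbind, unname(sys@Zlist)))
  P <- ncol(W)
  p <- ncol(sys@X)

  # CSR of W via CSC of t(W)
  Wt <- as(as(Matrix::t(W), "generalMatrix"), "CsparseMatrix")

  M <- as(as(Matrix::forceSymmetric(Matrix::crossprod(W)), "generalMatrix"),
          "CsparseMatrix")
  blockFrom <- integer(B); blockTo <- integer(B)
  Kfull <- vector("list", B)
  off <- p
  for (b in seq_len(B)) {
    q <- ncol(sys@Zlist[[b]])
    blockFrom[b] <- off
    blockTo[b] <- off + q
    Kb <- if (blocks[b] == "individual") sys@Ainv else Matrix::Diagonal(q)
    Kfull[[b]] <- embedBlock(Kb, P, off)
    off <- off + q
  }
  pattern <- M
  for (b in seq_len(B)) pattern <- pattern + Kfull[[b]]
  pattern <- as(as(pattern, "generalMatrix"), "CsparseMatrix")
  cp <- pattern@p; ci <- pattern@i
  mx <- alignToPattern(cp, ci, M)
  kx <- lapply(Kfull, function(K) alignToPattern(cp, ci, K))

  s2init <- rep(cfg@priorV, B)
  names(s2init) <- blocks
  if (!is.null(sigma2Init)) s2init[names(sigma2Init)] <- sigma2Init

  yBin <- if (threshold) as.integer(sys@y) else rep(NA_integer_, length(sys@y))
  yg <- if (threshold) numeric(length(sys@y)) else {
    if (is.null(yGauss)) sys@y else yGauss
  }
  if (!threshold && anyNA(yg)) stop("gaussian mode requires a complete response")

  set.seed(cfg@seed)
  res <- .gibbsChainCpp(
    Wt@p, Wt@i, Wt@x, cp, ci, mx, kx,
    blockFrom, blockTo, yBin, yg, threshold, sys@Rscale,
    rep(cfg@priorNu, B), rep(cfg@priorV, B),
    rep(cfg@parameterExpansion, B), rep(cfg@alphaV, B),
    cfg@fixVariances, unname(s2init),
    cfg@nIterations, cfg@burnIn, cfg@thin, cfg@recordLiabilities
  )

  vd <- cbind(res$variances, residual = rep(sys@Rscale, nret))
  colnames(vd) <- c(blocks, "residual")
  eff <- res$effects
  effNames <- colnames(sys@X)
  effBlocks <- rep(0L, p)
  for (b in seq_len(B)) {
    effNames <- c(effNames, paste0(blocks[b], ":", colnames(sys@Zlist[[b]])))
    effBlocks <- c(effBlocks, rep(b, ncol(sys@Zlist[[b]])))
  }
  colnames(eff) <- effNames

  new("PosteriorSamples",
      varianceDraws = vd, effectDraws = eff,
      liabilityDraws = res$liabilities, effectBlocks = effBlocks,
      meta = list(
        blocks = blocks, ids = sys@ids,
        individualOrder = if ("individual" %in% blocks)
          colnames(sys@Zlist[["individual"]]) else character(),
        spec = sys@spec, config = cfg, nRetained = nret
      ))
}

# place a q x q block at offset `off` inside a P x P zero sparse matrix
embedBlock <- function(Kb, P, off) {
  Kb <- as(as(Kb, "generalMatrix"), "CsparseMatrix")
  T <- as(Kb, "TsparseMatrix")
  Matrix::sparseMatrix(i = T@i + off + 1L, j = T@j + off + 1L, x = T@x,
                       dims = c(P, P))
}
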