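# MCMC configuration and presets.

#' Create an MCMC configuration
#'
#' @param nIterations,burnIn,thin chain length, discarded initial
#'   iterations, interval between retained draws.
#' @param seed master RNG seed.
#' @param priorV,priorNu inverse-gamma prior scale and degree of belief for
#'   each random-effect variance (scalar, applied to every block).
#' @param parameterExpansion use the parameter-expanded prior (working
#'   scale with Normal(0, alphaV) prior) — recommended for variances that
#'   may be small.
#' @param alphaV prior variance of the working scale parameter.
#' @param responseMode "threshold" (binary trait, latent liabilities,
#'   residual variance fixed) or "gaussian" (continuous response, used by
#'   the conjugate oracle tests).
#' @param fixVariances hold variance components at their initial values.
#' @param recordLiabilities record latent liabilities at retained draws.
#' @return an [MCMCConfig-class]
#' @export
mcmcConfig <- function(nIterations = 50000, burnIn = 5000, thin = 10,
                       seed = 1L, priorV = 1, priorNu = 1,
                       parameterExpansion = TRUE, alphaV = 1000,
                       responseMode = c("threshold", "gaussian"),
                       fixVariances = FALSE, recordLiabilities = FALSE) {
  new("MCMCConfig",
      nIterations = as.integer(nIterations), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed),
      priorV = priorV, priorNu = priorNu, alphaV = alphaV,
      parameterExpansion = parameterExpansion,
      responseMode = match.arg(responseMode),
      fixVariances = fixVariances, recordLiabilities = recordLiabilities)
}

#' Named MCMC presets
#'
#' \describe{
#'   \item{desk}{50,000 iterations, 5,000 burn-in, thin 10 — minutes-scale
#'     chains for routine work and simulation studies (4,500 retained).}
#'   \item{paper}{5.25 million iterations, 250,000 burn-in, thin 2,500 —
#'     the full-length any-cancer protocol (2,000 retained).}
#'   \item{paper_pdac}{6.25 million iterations, 250,000 burn-in, thin
#'     2,500 — the longer PDAC protocol (2,400 retained).}
#' }
#'
#' @param name preset name.
#' @param seed master RNG seed.
#' @param ... further arguments passed to [mcmcConfig()].
#' @return an [MCMCConfig-class]
#' @export
#' @examples
#' retainedSampleCount(mcmcPreset("paper"))
mcmcPreset <- function(name = c("desk", "paper", "paper_pdac"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(nIterations = 50000L, burnIn = 5000L, thin = 10L),
    paper = list(nIterations = 5250000L, burnIn = 250000L, thin = 2500L),
    paper_pdac = list(nIterations = 6250000L, burnIn = 250000L, thin = 2500L)
  )
  do.call(mcmcConfig, c(args, list(seed = seed), list(...)))
}

#' Number of retained posterior draws
#'
#' \code{floor((nIterations - burnIn) / thin)}.
#'
#' @param cfg an [MCMCConfig-class]
#' @return integer
#' @export
#' @examples
#' retainedSampleCount(mcmcConfig(5250000, 250000, 2500)) # 2000
retainedSampleCount <- function(cfg) {
  stopifnot(is(cfg, "MCMCConfig"))
  if (cfg@burnIn >= cfg@nIterations) stop("burn-in must be smaller than the iteration count")
  as.integer((cfg@nIterations - cfg@burnIn) %/% cfg@thin)
}
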