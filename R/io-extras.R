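# Plain-text exporters for downstream tooling.

#' Write the sparse A-inverse as a MatrixMarket triplet file
#'
#' @param x a sparse Matrix (e.g. from [aInverse()]) or a
#'   [Pedigree-class] (in which case A-inverse is computed first).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeAInverse <- function(x, path) {
  if (is(x, "Pedigree")) x <- aInverse(x)
  Matrix::writeMM(as(x, "generalMatrix"), path)
  invisible(path)
}

#' Write per-individual inbreeding coefficients as CSV
#'
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeInbreeding <- function(ped, path) {
  Fcoef <- inbreeding(ped)
  utils::write.csv(data.frame(id = names(Fcoef), F = unname(Fcoef)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a mixed-model solution as CSV (effect, level, estimate)
#'
#' @param sol an [MMESolution-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMMESolution <- function(sol, path) {
  rows <- data.frame(effect = "fixed", level = names(sol@beta),
                     estimate = unname(sol@beta), stringsAsFactors = FALSE)
  for (b in names(sol@u)) {
    rows <- rbind(rows, data.frame(effect = b, level = names(sol@u[[b]]),
                                   estimate = unname(sol@u[[b]]),
                                   stringsAsFactors = FALSE))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write / reload posterior samples as CSV + JSON meta
#'
#' One row per retained draw in \code{variances.csv} and
#' \code{effects.csv} (plus \code{liabilities.csv} when recorded);
#' bookkeeping in \code{meta.json}. [readPosteriorSamples()] rebuilds a
#' [PosteriorSamples-class] sufficient for all summary operations.
#'
#' @param ps a [PosteriorSamples-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writePosteriorSamples <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(ps@varianceDraws),
                   file.path(dir, "variances.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ps@effectDraws),
                   file.path(dir, "effects.csv"), row.names = FALSE)
  if (nrow(ps@liabilityDraws)) {
    utils::write.csv(as.data.frame(ps@liabilityDraws),
                     file.path(dir, "liabilities.csv"), row.names = FALSE)
  }
  cfg <- ps@meta$config
  meta <- list(
    blocks = ps@meta$blocks, ids = ps@meta$ids,
    individualOrder = ps@meta$individualOrder,
    effectBlocks = ps@meta$effectBlocks %||% ps@effectBlocks,
    nRetained = ps@meta$nRetained,
    config = if (is(cfg, "MCMCConfig")) list(
      nIterations = cfg@nIterations, burnIn = cfg@burnIn, thin = cfg@thin,
      seed = cfg@seed, responseMode = cfg@responseMode
    ) else cfg
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writePosteriorSamples
#' @export
readPosteriorSamples <- function(dir) {
  vd <- as.matrix(utils::read.csv(file.path(dir, "variances.csv"),
                                  check.names = FALSE))
  eff <- as.matrix(utils::read.csv(file.path(dir, "effects.csv"),
                                   check.names = FALSE))
  liabPath <- file.path(dir, "liabilities.csv")
  liab <- if (file.exists(liabPath)) {
    as.matrix(utils::read.csv(liabPath, check.names = FALSE))
  } else matrix(0, 0, 0)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  new("PosteriorSamples",
      varianceDraws = vd, effectDraws = eff, liabilityDraws = liab,
      effectBlocks = as.integer(meta$effectBlocks),
      meta = list(blocks = meta$blocks, ids = meta$ids,
                  individualOrder = meta$individualOrder,
                  config = meta$config, nRetained = meta$nRetained))
}
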