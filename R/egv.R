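# Estimated genetic values and the downstream discrimination/association
# analyses: parental-mean prediction, ROC/AUC, Kruskal-Wallis group
# comparison, Pearson correlation, family prevalence.

#' Per-individual estimated genetic values
#'
#' The EGV of an individual is the posterior mean of its additive-genetic
#' (individual random) effect across the retained draws — the pedigree
#' BLUP under the threshold model — reported with the interquartile range
#' of the same draws, joined to phenotype, cancer type and family.
#'
#' @param ps a [PosteriorSamples-class] with individual-effect draws.
#' @param ped the [Pedigree-class] the model was fitted to.
#' @return data.frame: id, egv, egvQ1, egvQ3, phenotype, cancerType,
#'   familyId (one row per modeled individual, pedigree order).
#' @export
egvTable <- function(ps, ped) {
  stopifnot(is(ps, "PosteriorSamples"), is(ped, "Pedigree"))
  bi <- which(ps@meta$blocks == "individual")
  if (!length(bi)) stop("no individual-effect draws recorded")
  cols <- which(ps@effectBlocks == bi)
  draws <- ps@effectDraws[, cols, drop = FALSE]
  ids <- ps@meta$individualOrder
  egv <- colMeans(draws)
  q <- apply(draws, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  m <- match(ped@id, ids)
  data.frame(
    id = ped@id, egv = egv[m], egvQ1 = q[1, m], egvQ3 = q[2, m],
    phenotype = ped@phenotype, cancerType = ped@cancerType,
    familyId = ped@familyId, stringsAsFactors = FALSE
  )
}

#' Parental-mean genetic value predictions
#'
#' Offspring inherit half of each parent's additive genetic value, so the
#' expected genetic value of an individual given its parents is the
#' parental mean. Returns \code{(egv_father + egv_mother) / 2} when both
#' parents are in the table; with \code{singleParentHalf = TRUE} an
#' individual with exactly one known parent gets \code{egv_parent / 2}
#' (the expectation with an average unknown mate), otherwise \code{NA};
#' founders are always \code{NA}.
#'
#' @param tab an EGV table from [egvTable()].
#' @param ped the [Pedigree-class].
#' @param singleParentHalf see above (default FALSE).
#' @return numeric vector of predictions aligned with \code{tab$id}.
#' @export
parentalMeanEGV <- function(tab, ped, singleParentHalf = FALSE) {
  egv <- setNames(tab$egv, tab$id)
  fa <- egv[ped@father]
  mo <- egv[ped@mother]
  pred <- (fa + mo) / 2
  if (singleParentHalf) {
    onlyFa <- !is.na(fa) & is.na(mo)
    onlyMo <- is.na(fa) & !is.na(mo)
    pred[onlyFa] <- fa[onlyFa] / 2
    pred[onlyMo] <- mo[onlyMo] / 2
  }
  unname(pred)
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney probability that a random case scores above a
#' random control, ties credited 1/2; the curve gives (FPR, TPR) at every
#' distinct threshold.
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels binary labels (1 = case, 0 = control); NAs in either
#'   vector drop the pair.
#' @return list: \code{auc}, and \code{curve} data.frame(threshold, fpr, tpr).
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.1, 0.8), c(1, 1, 0, 0))$auc # 0.875
rocAuc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / nPos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nNeg, 0)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr)))
}

#' Kruskal-Wallis comparison of values across groups
#'
#' Mid-rank Kruskal-Wallis statistic with tie correction,
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3 (N+1)\right] / C_{ties},}
#' with the p-value from the chi-square distribution on (groups - 1)
#' degrees of freedom, plus per-group medians and interquartile ranges.
#' Empty groups are dropped with a warning. When every value is tied the
#' statistic is 0 and p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return list: \code{summary} data.frame(group, n, median, q1, q3),
#'   \code{H}, \code{df}, \code{pValue}.
#' @export
groupCompare <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  f <- if (is.factor(groups)) groups[keep] else factor(as.character(groups[keep]))
  if (any(tabulate(f, nbins = nlevels(f)) == 0L)) {
    warning("empty group(s) dropped")
    f <- droplevels(f)
  }
  if (nlevels(f) < 2L) stop("need at least 2 non-empty groups")
  N <- length(values)
  r <- rank(values, ties.method = "average")
  Rj <- tapply(r, f, sum)
  nj <- tabulate(f)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(values)
  Cties <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H <- if (Cties > 0) H / Cties else 0
  df <- nlevels(f) - 1L
  p <- if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  summ <- do.call(rbind, lapply(levels(f), function(g) {
    v <- values[f == g]
    data.frame(group = g, n = length(v),
               median = round(stats::median(v), 3),
               q1 = round(stats::quantile(v, 0.25, names = FALSE), 3),
               q3 = round(stats::quantile(v, 0.75, names = FALSE), 3),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, H = H, df = df, pValue = p)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with a Fisher z-transform confidence
#' interval and a two-sided t-test p-value.
#'
#' @param x,y numeric vectors (n >= 3 complete pairs, non-constant).
#' @param conf confidence level (default 0.95).
#' @return list: \code{r}, \code{ci} c(lower, upper), \code{pValue}, \code{n}.
#' @export
pearsonCorrelation <- function(x, y, conf = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, ci = ci, pValue = p, n = n)
}

#' Family-level prevalence and its association with family EGV
#'
#' Prevalence (affected / members) per family, restricted to families
#' with at least \code{minSize} members — small families overestimate
#' prevalence — with excluded families reported separately. When an EGV
#' table is supplied, each retained family's median EGV is joined and the
#' Pearson correlation between family prevalence and median EGV is
#' computed.
#'
#' @param ped a [Pedigree-class].
#' @param egvTab optional EGV table from [egvTable()].
#' @param minSize minimum family size (default 20).
#' @return list: \code{families} data.frame(familyId, n, affected,
#'   prevalence[, medianEGV]), \code{excluded} data.frame(familyId, n),
#'   \code{correlation} ([pearsonCorrelation()] output or NULL).
#' @export
familyPrevalence <- function(ped, egvTab = NULL, minSize = 20) {
  fam <- factor(ped@familyId)
  n <- tabulate(fam)
  aff <- as.integer(tapply(ped@phenotype == 1L, fam, sum, na.rm = TRUE))
  tab <- data.frame(
    familyId = levels(fam), n = n, affected = aff,
    prevalence = aff / n, stringsAsFactors = FALSE
  )
  excluded <- tab[tab$n < minSize, c("familyId", "n")]
  tab <- tab[tab$n >= minSize, , drop = FALSE]
  if (!nrow(tab)) warning("all families below the minimum size")
  corr <- NULL
  if (!is.null(egvTab)) {
    med <- tapply(egvTab$egv, factor(egvTab$familyId, levels = tab$familyId),
                  stats::median, na.rm = TRUE)
    tab$medianEGV <- as.numeric(med)
    if (nrow(tab) >= 3L) {
      corr <- tryCatch(pearsonCorrelation(tab$prevalence, tab$medianEGV),
                       error = function(e) NULL)
    }
  }
  list(families = tab, excluded = excluded, correlation = corr)
}
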