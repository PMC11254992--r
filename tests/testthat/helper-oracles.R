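# Independent oracles and fixture builders used across the suite.

# --- fixture pedigrees (built in code) --------------------------------

trioPedigree <- function(phenotype = c(0L, 0L, 1L)) {
  newPedigree(
    id = c("s", "d", "c"), father = c(NA, NA, "s"), mother = c(NA, NA, "d"),
    sex = c("male", "female", "female"), phenotype = phenotype
  )
}

fullSibPedigree <- function() {
  newPedigree(
    id = c("s", "d", "k1", "k2"), father = c(NA, NA, "s", "s"),
    mother = c(NA, NA, "d", "d"),
    sex = c("male", "female", "male", "female")
  )
}

# sire mated to his own daughter: offspring F = 0.25
parentOffspringMating <- function() {
  newPedigree(
    id = c("s", "d", "c", "x"), father = c(NA, NA, "s", "s"),
    mother = c(NA, NA, "d", "c"),
    sex = c("male", "female", "female", "male")
  )
}

# half sibs (shared sire, different dams) mated: offspring F = 0.125
halfSibMating <- function() {
  newPedigree(
    id = c("s", "d1", "d2", "h1", "h2", "x"),
    father = c(NA, NA, NA, "s", "s", "h1"),
    mother = c(NA, NA, NA, "d1", "d2", "h2"),
    sex = c("male", "female", "female", "male", "female", "male")
  )
}

# random pedigree with optional inbred matings, independent of the
# package's simulator (pure structural generator for property tests)
randomPedigree <- function(n, seed, inbred = FALSE) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  nFounders <- max(4L, ceiling(n / 5))
  for (k in (nFounders + 1L):n) {
    males <- which(sex[seq_len(k - 1L)] == "male")
    females <- which(sex[seq_len(k - 1L)] == "female")
    if (!length(males) || !length(females)) next
    father[k] <- id[sample(males, 1)]
    mother[k] <- id[sample(females, 1)]
    if (!inbred) {
      # redraw once if an immediate self-loop ancestry was picked; the
      # parents-first indexing (parents always earlier) keeps it acyclic
    }
  }
  newPedigree(id = id, father = father, mother = mother, sex = sex,
              phenotype = sample(c(0L, 1L), n, replace = TRUE))
}

# --- oracles ----------------------------------------------------------

# dense GLS oracle: beta = (X'V^-1 X)^-1 X'V^-1 y, u_b = G_b Z_b' V^-1 (y - X beta)
glsOracle <- function(sys, vc) {
  X <- sys@X
  y <- sys@y
  n <- length(y)
  V <- diag(if ("residual" %in% names(vc)) vc[["residual"]] else sys@Rscale, n)
  Gs <- list()
  for (b in names(sys@Zlist)) {
    Z <- as.matrix(sys@Zlist[[b]])
    G <- if (b == "individual") {
      vc[[b]] * solve(as.matrix(sys@Ainv))
    } else {
      vc[[b]] * diag(ncol(Z))
    }
    Gs[[b]] <- G
    V <- V + Z %*% G %*% t(Z)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% beta
  u <- lapply(names(sys@Zlist), function(b) {
    as.numeric(Gs[[b]] %*% t(as.matrix(sys@Zlist[[b]])) %*% Vi %*% resid)
  })
  names(u) <- names(sys@Zlist)
  list(beta = as.numeric(beta), u = u)
}

# exhaustive pair-counting AUC oracle
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# gene-dropping Monte-Carlo estimate of the additive relationship matrix:
# drop two distinct alleles per founder, transmit one uniformly from each
# parent; A_ij is estimated as 2 * (mean allele-sharing probability).
geneDropOracle <- function(ped, nrep, seed) {
  set.seed(seed)
  ord <- sortParentsFirst(ped)
  idx <- match(ord, ped@id)
  fi <- match(ped@father[idx], ord)
  mi <- match(ped@mother[idx], ord)
  n <- length(ord)
  # allele matrices: nrep x n, maternal and paternal copies
  a1 <- matrix(0L, nrep, n)
  a2 <- matrix(0L, nrep, n)
  nextAllele <- 0L
  for (k in seq_len(n)) {
    if (is.na(fi[k])) {
      a1[, k] <- nextAllele + 1L
      nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a1[, k] <- ifelse(pick, a1[, fi[k]], a2[, fi[k]])
    }
    if (is.na(mi[k])) {
      a2[, k] <- nextAllele + 1L
      nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a2[, k] <- ifelse(pick, a1[, mi[k]], a2[, mi[k]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  se <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      # kinship: probability a random allele from i is IBD to one from j
      share <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * mean(share)
      se[i, j] <- se[j, i] <- 2 * stats::sd(share) / sqrt(nrep)
    }
  }
  list(A = A, se = se)
}

# hand-rolled Kruskal-Wallis H with mid-ranks and tie correction
kwOracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  f <- factor(groups)
  Rj <- tapply(r, f, sum)
  nj <- tabulate(f)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# conservative effective-sample-size lower bound across the columns of a
# draws matrix (AR-fit spectral estimate of the integrated autocorrelation)
effectiveDrawsLowerBound <- function(draws) {
  ess <- apply(draws, 2, function(x) {
    v <- stats::var(x)
    if (v == 0) return(length(x))
    fit <- try(stats::ar(x, aic = TRUE, order.max = 20), silent = TRUE)
    if (inherits(fit, "try-error")) return(length(x))
    s0 <- fit$var.pred / (1 - sum(fit$ar))^2
    max(10, length(x) * v / s0)
  })
  min(ess)
}

# reorder pedigree rows (links intact)
subsetPedigreeForTest <- function(ped, idx) {
  newPedigree(
    id = ped@id[idx], father = ped@father[idx], mother = ped@mother[idx],
    sex = ped@sex[idx], familyId = ped@familyId[idx],
    generation = ped@generation[idx], phenotype = ped@phenotype[idx],
    cancerType = ped@cancerType[idx]
  )
}

# small helper: binary response from a pedigree in pedigree order
pedResponse <- function(ped) {
  y <- ped@phenotype
  y[is.na(y)] <- 0L
  as.numeric(y)
}
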