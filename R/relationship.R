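# Additive (numerator) relationship matrix machinery.
#
# A is built by the tabular method in a parents-first ordering; A-inverse
# is assembled directly (never by inverting A) from Henderson's rules with
# inbreeding, using the Mendelian-sampling variance ratio
#   d_i = 0.5 - 0.25 (F_s + F_d)   both parents known
#       = 0.75 - 0.25 F_p          one parent known
#       = 1                        founder.

#' Additive relationship matrix from a pedigree
#'
#' Tabular method: founders have \eqn{A_{ii} = 1} and zero relationship to
#' earlier founders; for individual \eqn{k} with parents \eqn{s, d}
#' (missing parents contribute 0),
#' \eqn{A_{kj} = (A_{sj} + A_{dj})/2} for previously processed \eqn{j} and
#' \eqn{A_{kk} = 1 + A_{sd}/2}. Input order is irrelevant: the pedigree is
#' reordered parents-first internally.
#'
#' @param ped a [Pedigree-class] with an acyclic parent graph.
#' @return a [RelationshipMatrix-class] (ids in parents-first order).
#' @export
#' @examples
#' trio <- newPedigree(c("s", "d", "c"), c(NA, NA, "s"), c(NA, NA, "d"))
#' relA(additiveRelationship(trio))
additiveRelationship <- function(ped) {
  ord <- sortParentsFirst(ped)
  idx <- match(ord, ped@id)
  fi <- match(ped@father[idx], ord)
  mi <- match(ped@mother[idx], ord)
  n <- length(ord)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (k in seq_len(n)) {
    s <- fi[k]; d <- mi[k]
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      row <- numeric(k - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, prev]
      if (!is.na(d)) row <- row + 0.5 * A[d, prev]
      A[k, prev] <- row
      A[prev, k] <- row
    }
    A[k, k] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new("RelationshipMatrix", ids = ord, A = A, F = diag(A) - 1)
}

#' Inbreeding coefficients
#'
#' \eqn{F_i = A_{sd}/2} for the parents \eqn{s, d} of \eqn{i}; 0 when
#' either parent is unknown.
#'
#' @param ped a [Pedigree-class]
#' @return named numeric vector in the pedigree's input order.
#' @export
inbreeding <- function(ped) {
  rel <- additiveRelationship(ped)
  setNames(rel@F[match(ped@id, rel@ids)], ped@id)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles \eqn{A^{-1}} directly by Henderson's rules, accounting for
#' parental inbreeding through the Mendelian-sampling variance ratio
#' \eqn{d_i}: add \eqn{1/d_i} at \eqn{(i,i)}, \eqn{-1/(2 d_i)} at
#' \eqn{(i, p)} for each known parent \eqn{p}, and \eqn{1/(4 d_i)} at
#' every known parent pair \eqn{(p, q)} (including \eqn{p = q}).
#'
#' @param ped a [Pedigree-class] with an acyclic parent graph.
#' @return symmetric sparse \code{Matrix} with ids (parents-first) as
#'   dimnames, same ordering as [additiveRelationship()].
#' @export
aInverse <- function(ped) {
  ord <- sortParentsFirst(ped)
  idx <- match(ord, ped@id)
  fi <- match(ped@father[idx], ord)
  mi <- match(ped@mother[idx], ord)
  Fcoef <- inbreeding(ped)[ped@id[idx]]
  n <- length(ord)

  d <- numeric(n)
  both <- !is.na(fi) & !is.na(mi)
  one <- xor(is.na(fi), is.na(mi))
  d[both] <- 0.5 - 0.25 * (Fcoef[fi[both]] + Fcoef[mi[both]])
  knownOne <- ifelse(is.na(fi), mi, fi)
  d[one] <- 0.75 - 0.25 * Fcoef[knownOne[one]]
  d[!both & !one] <- 1

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (k in seq_len(n)) {
    w <- 1 / d[k]
    push(k, k, w)
    parents <- c(fi[k], mi[k])
    parents <- parents[!is.na(parents)]
    for (p in parents) push(k, p, -0.5 * w)
    if (length(parents)) {
      grid <- expand.grid(p = parents, q = parents)
      push(grid$p, grid$q, rep(0.25 * w, nrow(grid)))
    }
  }
  # accumulate duplicates; keep lower triangle for the symmetric class
  low <- ii >= jj
  Ainv <- Matrix::sparseMatrix(
    i = ii[low], j = jj[low], x = xx[low], dims = c(n, n),
    dimnames = list(ord, ord), symmetric = TRUE
  )
  Ainv
}
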