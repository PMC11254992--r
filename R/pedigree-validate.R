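# Structural validation, off-kindred exclusion and topological ordering.

pedParentEdges <- function(ped) {
  # data.frame(child index, parent index) over resolved links
  fi <- match(ped@father, ped@id)
  mi <- match(ped@mother, ped@id)
  rbind(
    data.frame(child = which(!is.na(fi)), parent = fi[!is.na(fi)]),
    data.frame(child = which(!is.na(mi)), parent = mi[!is.na(mi)])
  )
}

#' Validate a pedigree
#'
#' Audits structural soundness and collects findings into a
#' [ValidationReport-class] instead of throwing. Errors: duplicate ids,
#' self-parentage, unresolved parent references, cycles in the parent
#' graph, parent-sex inconsistency (a known-sex father that is not male, a
#' known-sex mother that is not female). Warnings: generation indices that
#' are not strictly greater than each known parent's (registry data may
#' legitimately violate monotonicity, so this is flagged, not fatal).
#'
#' @param ped a [Pedigree-class]
#' @return a [ValidationReport-class]; passes iff no errors.
#' @export
validatePedigree <- function(ped) {
  err <- list(); wrn <- list()
  add <- function(lst, rule, id, message) {
    c(lst, list(data.frame(rule = rule, id = id, message = message,
                           stringsAsFactors = FALSE)))
  }
  dup <- unique(ped@id[duplicated(ped@id)])
  if (length(dup)) err <- add(err, "duplicate id", dup, "individual appears more than once")

  selfp <- which(!is.na(ped@father) & ped@father == ped@id |
                 !is.na(ped@mother) & ped@mother == ped@id)
  if (length(selfp)) err <- add(err, "self-parentage", ped@id[selfp], "individual is its own parent")

  for (side in c("father", "mother")) {
    p <- slot(ped, side)
    unresolved <- which(!is.na(p) & !(p %in% ped@id))
    if (length(unresolved)) {
      err <- add(err, "unknown parent", ped@id[unresolved],
                 paste0(side, " '", p[unresolved], "' not in pedigree"))
    }
    sexNeeded <- if (side == "father") "male" else "female"
    pidx <- match(p, ped@id)
    bad <- which(!is.na(pidx) & ped@sex[ifelse(is.na(pidx), 1L, pidx)] != sexNeeded &
                 ped@sex[ifelse(is.na(pidx), 1L, pidx)] != "unknown")
    if (length(bad)) {
      err <- add(err, "parent sex", ped@id[bad],
                 paste0(side, " '", p[bad], "' is not ", sexNeeded))
    }
  }

  # cycle detection on the resolved, non-self parent graph
  cyc <- pedCycleMembers(ped)
  if (length(cyc)) err <- add(err, "cycle", cyc, "individual lies on a parent-graph cycle")

  if (!length(cyc)) {
    fi <- match(ped@father, ped@id); mi <- match(ped@mother, ped@id)
    for (i in seq_along(ped@id)) {
      for (p in c(fi[i], mi[i])) {
        if (!is.na(p) && !is.na(ped@generation[i]) && !is.na(ped@generation[p]) &&
            ped@generation[i] <= ped@generation[p]) {
          wrn <- add(wrn, "generation order", ped@id[i],
                     paste0("generation not greater than parent '", ped@id[p], "'"))
        }
      }
    }
  }

  empty <- data.frame(rule = character(), id = character(), message = character(),
                      stringsAsFactors = FALSE)
  errors <- if (length(err)) do.call(rbind, err) else empty
  n <- length(ped@id)
  new("ValidationReport",
      errors = errors,
      warnings = if (length(wrn)) do.call(rbind, wrn) else empty,
      counts = c(read = n, kept = n, dropped = 0L))
}

# ids of individuals lying on a parent-graph cycle (empty if acyclic)
pedCycleMembers <- function(ped) {
  edges <- pedParentEdges(ped)
  edges <- edges[edges$child != edges$parent, , drop = FALSE]
  if (!nrow(edges)) return(character())
  g <- igraph::graph_from_edgelist(
    cbind(ped@id[edges$parent], ped@id[edges$child]), directed = TRUE
  )
  if (igraph::is_dag(g)) return(character())
  comp <- igraph::components(g, mode = "strong")
  keep <- which(comp$csize > 1L)
  names(comp$membership)[comp$membership %in% keep]
}

#' Exclude off-kindred individuals
#'
#' Within each family, builds the undirected parent-offspring graph,
#' removes isolated individuals (no parents and no offspring recorded),
#' and keeps only the connected component(s) containing at least one
#' affected individual — or, if the family has no affected member, its
#' largest component. Idempotent.
#'
#' @param ped a validated [Pedigree-class]
#' @return the reduced [Pedigree-class]; the number of removed
#'   individuals is attached as attribute \code{"dropped"}.
#' @export
excludeOffKindred <- function(ped) {
  n <- length(ped@id)
  edges <- pedParentEdges(ped)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ped@id[edges$parent], to = ped@id[edges$child]),
    directed = FALSE, vertices = data.frame(name = ped@id)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[ped@id]
  deg <- igraph::degree(g)[ped@id]
  keep <- rep(FALSE, n)
  for (fam in unique(ped@familyId)) {
    rows <- which(ped@familyId == fam & deg > 0)
    if (!length(rows)) next
    comps <- unique(membership[rows])
    affectedComps <- unique(membership[rows][ped@phenotype[rows] %in% 1L])
    if (length(affectedComps)) {
      keep[rows[membership[rows] %in% affectedComps]] <- TRUE
    } else {
      sizes <- table(membership[rows])
      best <- as.integer(names(sizes)[which.max(sizes)])
      keep[rows[membership[rows] == best]] <- TRUE
    }
  }
  if (!any(keep)) stop("family fully excluded: no connected members remain")
  out <- subsetPedigree(ped, which(keep))
  attr(out, "dropped") <- sum(!keep)
  out
}

subsetPedigree <- function(ped, idx) {
  kept <- ped@id[idx]
  clearParent <- function(p) ifelse(p %in% kept, p, NA_character_)
  new("Pedigree",
    id = ped@id[idx],
    father = clearParent(ped@father[idx]),
    mother = clearParent(ped@mother[idx]),
    sex = ped@sex[idx], familyId = ped@familyId[idx],
    generation = ped@generation[idx], phenotype = ped@phenotype[idx],
    cancerType = ped@cancerType[idx], dialect = ped@dialect,
    readReport = ped@readReport
  )
}

#' Parents-first topological ordering
#'
#' Orders individuals so that every parent precedes all of its offspring.
#' Deterministic: individuals are ranked by depth in the parent graph
#' (founders 0, otherwise 1 + max parent depth) with ties broken by input
#' order.
#'
#' @param ped a [Pedigree-class] with an acyclic parent graph.
#' @return character vector of ids in parents-first order.
#' @export
sortParentsFirst <- function(ped) {
  if (length(pedCycleMembers(ped))) stop("cycle in parent graph; no parents-first order exists")
  depth <- pedDepth(ped)
  ped@id[order(depth, seq_along(ped@id))]
}

pedDepth <- function(ped) {
  n <- length(ped@id)
  fi <- match(ped@father, ped@id)
  mi <- match(ped@mother, ped@id)
  depth <- rep(0L, n)
  repeat {
    pf <- ifelse(is.na(fi), -1L, depth[ifelse(is.na(fi), 1L, fi)])
    pm <- ifelse(is.na(mi), -1L, depth[ifelse(is.na(mi), 1L, mi)])
    new <- pmax(0L, pmax(pf, pm) + 1L)
    if (all(new == depth)) break
    depth <- new
  }
  depth
}
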