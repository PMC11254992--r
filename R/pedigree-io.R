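# Reading, writing and constructing pedigrees.
#
# Supported dialects:
#   fam     : PLINK-style whitespace file, 6 columns
#             family id father mother sex phenotype
#             sex 1=male 2=female 0=unknown; phenotype 2=affected
#             1=unaffected 0/-9=unknown; missing parent "0".
#   linkage : LINKAGE pre-makeped; same 6 leading columns and codes.
#   csv     : header family_id,id,father_id,mother_id,sex,generation,
#             phenotype,cancer_type; sex female/male/unknown; phenotype
#             0/1/NA; missing parent empty/NA; generation/cancer_type
#             optional.

#' Construct a pedigree from vectors
#'
#' Low-level constructor. Missing parents are \code{NA}; when
#' \code{generation} is missing it is inferred as 1 + the maximum known
#' parent generation (founders 0).
#'
#' @param id character individual ids (unique).
#' @param father,mother parent ids or NA.
#' @param sex "female"/"male"/"unknown" (default unknown).
#' @param familyId family identifier (default one family "F1").
#' @param generation integer generation index or NULL to infer.
#' @param phenotype 0/1/NA affected status.
#' @param cancerType optional cancer-type labels.
#' @param dialect source-format tag.
#' @param readReport parse-stage findings (internal).
#' @return a [Pedigree-class]
#' @export
#' @examples
#' trio <- newPedigree(
#'   id = c("s", "d", "c"), father = c(NA, NA, "s"), mother = c(NA, NA, "d"),
#'   sex = c("male", "female", "female"), phenotype = c(0, 0, 1)
#' )
#' trio
newPedigree <- function(id, father, mother,
                        sex = rep("unknown", length(id)),
                        familyId = rep("F1", length(id)),
                        generation = NULL,
                        phenotype = rep(NA_integer_, length(id)),
                        cancerType = rep(NA_character_, length(id)),
                        dialect = "csv", readReport = list()) {
  id <- as.character(id)
  normParent <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & (p == "" | p == "0")] <- NA_character_
    p
  }
  gen <- if (is.null(generation)) rep(NA_integer_, length(id)) else {
    suppressWarnings(as.integer(generation))
  }
  ped <- new("Pedigree",
    id = id, father = normParent(father), mother = normParent(mother),
    sex = as.character(sex), familyId = as.character(familyId),
    generation = gen, phenotype = as.integer(phenotype),
    cancerType = as.character(cancerType), dialect = dialect,
    readReport = readReport
  )
  if (all(is.na(ped@generation))) {
    # leave NA when no consistent assignment exists (e.g. a cycle, which
    # validatePedigree will flag)
    ped@generation <- tryCatch(inferGenerations(ped),
                               error = function(e) ped@generation)
  }
  ped
}

#' Infer generation indices from parent links
#'
#' Founders (no known parent in the pedigree) get generation 0; every
#' other individual gets 1 + the maximum generation among its known
#' parents. Requires an acyclic parent graph.
#'
#' @param ped a [Pedigree-class]
#' @return integer vector of generation indices
#' @export
inferGenerations <- function(ped) {
  n <- length(ped@id)
  fi <- match(ped@father, ped@id)
  mi <- match(ped@mother, ped@id)
  gen <- rep(0L, n)
  for (pass in seq_len(n + 1L)) {
    pg <- pmax(ifelse(is.na(fi), -1L, gen[ifelse(is.na(fi), 1L, fi)]),
               ifelse(is.na(mi), -1L, gen[ifelse(is.na(mi), 1L, mi)]))
    new <- pmax(0L, pg + 1L)
    if (all(new == gen)) return(gen)
    gen <- new
    if (pass > n) stop("cycle in parent graph; generations undefined")
  }
  gen
}

#' Read a pedigree file
#'
#' Parses a pedigree in one of three text dialects (see the package
#' vignette), normalizes missing-parent and sex/phenotype codes, and
#' collects rather than throws non-fatal problems: a parent reference
#' that does not resolve within the file is recorded as an "unknown
#' parent" error and, unless \code{strict = TRUE}, the individual is kept
#' with that parent set to missing.
#'
#' @param path file path.
#' @param dialect "fam", "linkage" or "csv".
#' @param strict if TRUE, any collected error aborts the read.
#' @return a [Pedigree-class]; parse findings via [readReport()].
#' @export
readPedigree <- function(path, dialect = c("fam", "linkage", "csv"),
                         strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect %in% c("fam", "linkage")) {
    raw <- tryCatch(
      utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character"),
      error = function(e) stop("malformed ", dialect, " file: ", conditionMessage(e))
    )
    if (ncol(raw) < 6L) {
      stop("malformed ", dialect, " file: expected >= 6 columns, got ", ncol(raw))
    }
    names(raw)[1:6] <- c("family_id", "id", "father_id", "mother_id", "sex", "phenotype")
    sex <- c("0" = "unknown", "1" = "male", "2" = "female")[raw$sex]
    sex[is.na(sex)] <- "unknown"
    phen <- rep(NA_integer_, nrow(raw))
    phen[raw$phenotype == "2"] <- 1L
    phen[raw$phenotype == "1"] <- 0L
    df <- data.frame(
      family_id = raw$family_id, id = raw$id, father_id = raw$father_id,
      mother_id = raw$mother_id, sex = sex, generation = NA_integer_,
      phenotype = phen, cancer_type = NA_character_, stringsAsFactors = FALSE
    )
  } else {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("", "NA")),
      error = function(e) stop("malformed csv file: ", conditionMessage(e))
    )
    need <- c("family_id", "id", "father_id", "mother_id", "sex", "phenotype")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("csv dialect missing column(s): ", paste(miss, collapse = ", "))
    if (!"generation" %in% names(df)) df$generation <- NA_character_
    if (!"cancer_type" %in% names(df)) df$cancer_type <- NA_character_
    df$sex <- ifelse(is.na(df$sex), "unknown", df$sex)
    bad <- which(!df$sex %in% SEX_LEVELS)
    if (length(bad)) stop("malformed csv row ", bad[1] + 1L, ": invalid sex '", df$sex[bad[1]], "'")
    badp <- which(!is.na(df$phenotype) & !df$phenotype %in% c("0", "1"))
    if (length(badp)) {
      stop("malformed csv row ", badp[1] + 1L, ": invalid phenotype '", df$phenotype[badp[1]], "'")
    }
  }

  errors <- data.frame(rule = character(), id = character(), message = character(),
                       stringsAsFactors = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    errors <- rbind(errors, data.frame(
      rule = "duplicate id", id = unique(dup),
      message = "individual appears more than once", stringsAsFactors = FALSE
    ))
  }
  normParent <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & (p == "" | p == "0")] <- NA_character_
    p
  }
  df$father_id <- normParent(df$father_id)
  df$mother_id <- normParent(df$mother_id)
  for (col in c("father_id", "mother_id")) {
    unresolved <- !is.na(df[[col]]) & !(df[[col]] %in% df$id)
    if (any(unresolved)) {
      errors <- rbind(errors, data.frame(
        rule = "unknown parent", id = df$id[unresolved],
        message = paste0(sub("_id$", "", col), " '", df[[col]][unresolved],
                         "' not in pedigree"), stringsAsFactors = FALSE
      ))
      df[[col]][unresolved] <- NA_character_
    }
  }
  if (strict && nrow(errors)) {
    stop("pedigree read failed under strict mode: ", errors$rule[1], " (",
         errors$id[1], ")")
  }
  newPedigree(
    id = df$id, father = df$father_id, mother = df$mother_id, sex = df$sex,
    familyId = df$family_id, generation = df$generation,
    phenotype = df$phenotype, cancerType = df$cancer_type, dialect = dialect,
    readReport = list(errors = errors,
                      counts = c(read = nrow(df), kept = nrow(df), dropped = 0L))
  )
}

#' Write a pedigree file
#'
#' Inverse of [readPedigree()] for the retained fields of each dialect.
#'
#' @param ped a [Pedigree-class]
#' @param path output file path.
#' @param dialect "fam", "linkage" or "csv".
#' @return invisibly, the path.
#' @export
writePedigree <- function(ped, path, dialect = c("fam", "linkage", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect %in% c("fam", "linkage")) {
    sex <- c(female = "2", male = "1", unknown = "0")[ped@sex]
    phen <- ifelse(is.na(ped@phenotype), "0", ifelse(ped@phenotype == 1L, "2", "1"))
    out <- data.frame(
      ped@familyId, ped@id,
      ifelse(is.na(ped@father), "0", ped@father),
      ifelse(is.na(ped@mother), "0", ped@mother),
      sex, phen
    )
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = " ")
  } else {
    utils::write.csv(pedToDataFrame(ped), path, row.names = FALSE, na = "")
  }
  invisible(path)
}
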