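# Reading, validating, cleaning and ordering pedigrees.

test_that("fam dialect decodes sex/phenotype codes and missing parents", {
  path <- withr::local_tempfile(fileext = ".fam")
  writeLines(c(
    "F1 s 0 0 1 1",
    "F1 d 0 0 2 1",
    "F1 c s d 2 2"
  ), path)
  ped <- readPedigree(path, "fam")
  expect_equal(nIndividuals(ped), 3L)
  expect_equal(sum(is.na(ped@father) & is.na(ped@mother)), 2L) # founders
  expect_equal(ped@sex, c("male", "female", "female"))
  expect_equal(ped@phenotype, c(0L, 0L, 1L))
  expect_equal(ped@generation, c(0L, 0L, 1L)) # inferred
})

test_that("unknown parent is collected, not thrown, unless strict", {
  path <- withr::local_tempfile(fileext = ".fam")
  writeLines(c(
    "F1 a 0 0 1 1",
    "F1 b ghost 0 2 1"
  ), path)
  ped <- readPedigree(path, "fam")
  rep <- readReport(ped)
  expect_equal(rep$errors$rule, "unknown parent")
  expect_true(is.na(ped@father[2])) # retained with parent cleared
  expect_error(readPedigree(path, "fam", strict = TRUE), "unknown parent")
})

test_that("csv dialect passes generations and cancer types through", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "family_id,id,father_id,mother_id,sex,generation,phenotype,cancer_type",
    "F1,s,,,male,0,0,",
    "F1,d,,,female,1,0,",
    "F1,c,s,d,female,1,1,PDAC"
  ), path)
  ped <- readPedigree(path, "csv")
  expect_equal(ped@generation, c(0L, 1L, 1L)) # verbatim, even non-monotone
  expect_equal(ped@cancerType, c(NA, NA, "PDAC"))
  expect_equal(ped@phenotype, c(0L, 0L, 1L))
})

test_that("malformed input names the problem", {
  path <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("F1 a 0 0", "F1 b 0 0 1 1 extra junk bad"), path)
  expect_error(readPedigree(path, "fam"), "malformed")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "family_id,id,father_id,mother_id,sex,generation,phenotype,cancer_type",
    "F1,a,,,male,0,7,"
  ), path2)
  expect_error(readPedigree(path2, "csv"), "row 2")
})

test_that("read -> write -> read round-trips each dialect", {
  for (dialect in c("fam", "linkage", "csv")) {
    cfg <- simulationConfig(nFamilies = 3, seed = 42)
    ped <- simulatePhenotypes(simulatePedigree(cfg), cfg)$ped
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    writePedigree(ped, path, dialect)
    back <- readPedigree(path, dialect)
    expect_equal(back@id, ped@id)
    expect_equal(back@father, ped@father)
    expect_equal(back@mother, ped@mother)
    expect_equal(back@sex, ped@sex)
    expect_equal(back@phenotype, ped@phenotype)
    if (dialect == "csv") expect_equal(back@generation, ped@generation)
  }
})

test_that("validation flags self-parentage, cycles, duplicates, parent sex", {
  selfp <- newPedigree(c("a", "b"), c("a", NA), c(NA, NA))
  expect_true("self-parentage" %in% validationErrors(validatePedigree(selfp))$rule)

  cyc <- newPedigree(c("a", "b"), c("b", "a"), c(NA, NA))
  expect_true("cycle" %in% validationErrors(validatePedigree(cyc))$rule)

  dup <- newPedigree(c("a", "a"), c(NA, NA), c(NA, NA))
  expect_true("duplicate id" %in% validationErrors(validatePedigree(dup))$rule)

  badSex <- newPedigree(c("s", "d", "c"), c(NA, NA, "d"), c(NA, NA, "s"),
                        sex = c("male", "female", "female"))
  expect_true("parent sex" %in% validationErrors(validatePedigree(badSex))$rule)
})

test_that("clean three-generation pedigree validates with no errors", {
  ped <- halfSibMating()
  rep <- validatePedigree(ped)
  expect_true(validationPassed(rep))
  expect_equal(nrow(validationWarnings(rep)), 0L)
})

test_that("non-monotone generations warn but do not fail", {
  ped <- newPedigree(c("s", "d", "c"), c(NA, NA, "s"), c(NA, NA, "d"),
                     generation = c(0L, 0L, 0L))
  rep <- validatePedigree(ped)
  expect_true(validationPassed(rep))
  expect_true("generation order" %in% validationWarnings(rep)$rule)
})

test_that("off-kindred exclusion keeps affected components, drops isolated", {
  # connected family of 5 (one affected) + isolated unaffected singleton
  ped <- newPedigree(
    id = c("s", "d", "c1", "c2", "c3", "lone"),
    father = c(NA, NA, "s", "s", "s", NA),
    mother = c(NA, NA, "d", "d", "d", NA),
    phenotype = c(0L, 0L, 1L, 0L, 0L, 0L)
  )
  out <- excludeOffKindred(ped)
  expect_equal(nIndividuals(out), 5L)
  expect_equal(attr(out, "dropped"), 1L)
  expect_false("lone" %in% pedIds(out))
})

test_that("components without affected members are dropped when another has one", {
  ped <- newPedigree(
    id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    father = c(NA, NA, "a1", NA, NA, "b1"),
    mother = c(NA, NA, "a2", NA, NA, "b2"),
    phenotype = c(0L, 0L, 1L, 0L, 0L, 0L)
  )
  out <- excludeOffKindred(ped)
  expect_setequal(pedIds(out), c("a1", "a2", "a3"))
})

test_that("off-kindred exclusion is the identity on connected families and idempotent", {
  cfg <- simulationConfig(nFamilies = 4, seed = 11)
  ped <- simulatePhenotypes(simulatePedigree(cfg), cfg)$ped
  once <- excludeOffKindred(ped)
  expect_equal(pedIds(once), pedIds(ped)) # generator families are connected
  twice <- excludeOffKindred(once)
  expect_equal(pedToDataFrame(twice), pedToDataFrame(once))
})

test_that("fully excluded family errors", {
  lone <- newPedigree(c("a", "b"), c(NA, NA), c(NA, NA), phenotype = c(0L, 0L))
  expect_error(excludeOffKindred(lone), "fully excluded")
})

test_that("parents-first ordering places every parent before its offspring", {
  # child listed first in input
  ped <- newPedigree(c("c", "s", "d"), c("s", NA, NA), c("d", NA, NA))
  ord <- sortParentsFirst(ped)
  expect_equal(ord[3], "c")

  founders <- newPedigree(c("x", "y", "z"), rep(NA, 3), rep(NA, 3))
  expect_equal(sortParentsFirst(founders), c("x", "y", "z")) # input order

  chain <- newPedigree(c("A", "B", "C"), c(NA, "A", "B"), rep(NA, 3))
  expect_equal(sortParentsFirst(chain), c("A", "B", "C"))

  for (seed in 1:5) {
    ped <- randomPedigree(40, seed)
    ord <- sortParentsFirst(ped)
    pos <- match(ped@id, ord)
    for (k in seq_along(ped@id)) {
      for (p in c(ped@father[k], ped@mother[k])) {
        if (!is.na(p)) expect_lt(pos[match(p, ped@id)], pos[k])
      }
    }
  }
})

test_that("cyclic pedigrees cannot be ordered", {
  cyc <- newPedigree(c("a", "b"), c("b", "a"), c(NA, NA))
  expect_error(sortParentsFirst(cyc), "cycle")
})
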