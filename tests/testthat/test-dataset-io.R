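writeTestCSV <- function(df) {
  tf <- tempfile(fileext = ".csv")
  write.csv(df, tf, row.names = FALSE)
  tf
}

test_that("parsing keeps every row and flags unparseable SMILES", {
  tf <- writeTestCSV(data.frame(
    id = c("a", "b", "c"), name = c("ethanol", "broken", "benzene"),
    smiles = c("CCO", "C1CC", "c1ccccc1"),
    approval_year = c(2001L, 2010L, 2022L)
  ))
  ds <- parseDataset(tf)
  rec <- drugRecords(ds)
  expect_equal(nCompounds(ds), 3L)
  expect_equal(sum(is.na(rec$canonical_smiles)), 1L)
  expect_true(rec$excluded[rec$id == "b"])
  expect_equal(rec$exclusion_reason[rec$id == "b"], "descriptor-failure")
})

test_that("empty and malformed inputs raise explicit errors", {
  empty <- writeTestCSV(data.frame(id = character(), smiles = character(),
                                   approval_year = integer()))
  expect_error(parseDataset(empty), "empty dataset")
  nocol <- writeTestCSV(data.frame(id = "a", approval_year = 2001L))
  expect_error(parseDataset(nocol), "missing")
  expect_error(parseDataset(tempfile()), "not found")
  badyear <- writeTestCSV(data.frame(id = "a", smiles = "CCO",
                                     approval_year = 1995L))
  expect_error(parseDataset(badyear), "approval_year")
})

test_that("salts are reduced to the largest organic fragment", {
  tf <- writeTestCSV(data.frame(id = "s", smiles = "CC(=O)O.[Na]",
                                approval_year = 2005L))
  rec <- drugRecords(parseDataset(tf))
  expect_true(rec$fragment_stripped)
  expect_equal(rec$canonical_smiles, canonicalSmiles("CC(=O)O"))
})

test_that("exclusions partition the parsed set and preserve order", {
  tf <- writeTestCSV(data.frame(
    id = sprintf("d%d", 1:5),
    smiles = c("CCO", "c1ccccc1", "CCN", "CCC", "CCOC"),
    approval_year = c(2001L, 2005L, 2010L, 2015L, 2020L),
    excluded = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    exclusion_reason = c(NA, "not-absorbed-GI", NA,
                         "combination-of-older-drugs", NA)
  ))
  ds <- parseDataset(tf)
  as <- applyExclusions(ds)
  expect_s4_class(as, "AnalysisSet")
  expect_equal(nCompounds(ds), nCompounds(as) + provenance(as)$n_excluded)
  expect_equal(drugRecords(as)$id, c("d1", "d3", "d5"))
  counts <- provenance(as)$exclusion_counts
  expect_equal(counts[["not-absorbed-GI"]], 1L)
  expect_equal(counts[["combination-of-older-drugs"]], 1L)

  # no flags -> identity
  tf2 <- writeTestCSV(data.frame(id = c("x", "y"), smiles = c("CCO", "CCN"),
                                 approval_year = c(2001L, 2002L)))
  ds2 <- parseDataset(tf2)
  expect_equal(drugRecords(applyExclusions(ds2))$id, drugRecords(ds2)$id)

  # all flagged -> empty set with a warning
  tf3 <- writeTestCSV(data.frame(id = "x", smiles = "CCO",
                                 approval_year = 2001L, excluded = TRUE,
                                 exclusion_reason = "not-absorbed-GI"))
  expect_warning(as3 <- applyExclusions(parseDataset(tf3)), "empty")
  expect_equal(nCompounds(as3), 0L)
})

test_that("structures round-trip through SDF with properties intact", {
  tf <- writeTestCSV(data.frame(
    id = c("m1", "m2"), name = c("aspirin", "macro"),
    smiles = c("CC(=O)Oc1ccccc1C(=O)O", "C1CCCCCCCCCCC1"),
    approval_year = c(2003L, 2018L)
  ))
  as <- applyExclusions(parseDataset(tf))
  sf <- tempfile(fileext = ".sdf")
  writeStructures(as, sf)
  back <- ChemmineR::read.SDFset(sf)
  expect_equal(length(back), 2L)
  blk <- ChemmineR::datablock(back[[1]])
  expect_equal(unname(blk["id"]), "m1")
  expect_equal(unname(blk["approval_year"]), "2003")

  # macrocyclic ring size survives the round trip
  mac <- ChemmineR::sdf2smiles(back[2])
  expect_true(isMacrocycle(canonicalSmiles(as.character(mac))))

  # empty set -> valid empty file
  tf0 <- writeTestCSV(data.frame(id = "x", smiles = "CCO",
                                 approval_year = 2001L, excluded = TRUE,
                                 exclusion_reason = "not-absorbed-GI"))
  as0 <- suppressWarnings(applyExclusions(parseDataset(tf0)))
  sf0 <- tempfile(fileext = ".sdf")
  writeStructures(as0, sf0)
  expect_true(file.exists(sf0))
})

test_that("parse -> write -> parse preserves id, year and canonical SMILES", {
  lib <- cachedLibrary()
  rec <- drugRecords(lib)[1:10, ]
  tf <- writeTestCSV(as.data.frame(rec[, c("id", "smiles", "approval_year")]))
  ds <- parseDataset(tf)
  out <- drugRecords(ds)
  expect_equal(out$id, rec$id)
  expect_equal(out$approval_year, rec$approval_year)
  expect_equal(out$canonical_smiles, rec$canonical_smiles)
})
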