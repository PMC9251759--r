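test_that("validatePsmTable reports every invariant violation with its row", {
  ok <- psmTable(spectrum_id = "s1", peptide = "ASK",
                 mod_positions = list(2L), ptm_probabilities = list(0.9),
                 psm_probability = 0.95)
  expect_identical(nrow(validatePsmTable(ok)), 0L)

  bad <- psmTable(
    spectrum_id = c("a", "b", "c", "d"),
    peptide = c("ASK", "ASK", "ASK", "ASK"),
    mod_positions = list(4L, c(3L, 2L), 2L, 2L),
    ptm_probabilities = list(0.9, c(0.9, 0.9), c(0.9, 0.8), 0.9),
    psm_probability = c(0.9, 0.9, 0.9, 1.3))
  report <- validatePsmTable(bad)
  expect_true(any(report$row == 1 & grepl("out of range", report$message)))
  expect_true(any(report$row == 2 & grepl("increasing", report$message)))
  expect_true(any(report$row == 3 & grepl("mismatch", report$message)))
  expect_true(any(report$row == 4 & grepl("outside \\[0,1\\]", report$message)))
  ## validation never mutates its input
  expect_identical(bad$psm_probability[4], 1.3)
})

test_that("missing PSM probability needs a score, and streams are not mixed", {
  scoreOnly <- psmTable(spectrum_id = "s", peptide = "ASK",
                        mod_positions = list(2L),
                        ptm_probabilities = list(0.8),
                        psm_probability = NA_real_, psm_score = 12.5)
  expect_identical(nrow(validatePsmTable(scoreOnly)), 0L)

  neither <- psmTable(spectrum_id = "s", peptide = "ASK",
                      mod_positions = list(2L),
                      ptm_probabilities = list(0.8))
  expect_true(any(grepl("requires a raw score",
                        validatePsmTable(neither)$message)))

  mixed <- psmTable(spectrum_id = c("a", "b"), peptide = c("ASK", "ASK"),
                    mod_positions = list(2L, 2L),
                    ptm_probabilities = list(0.8, 0.8),
                    psm_probability = c(0.9, NA), psm_score = c(NA, 3))
  expect_true(any(grepl("mixes", validatePsmTable(mixed)$message)))
})

test_that("interchange TSV round-trips identical field values", {
  psms <- psmTable(
    spectrum_id = c("sp 1", "sp2"), peptide = c("ASTYK", "GSAK"),
    charge = c(2L, 3L),
    mod_positions = list(c(2L, 3L), 2L),
    ptm_probabilities = list(c(0.875, 0.5), 0.25),
    psm_probability = c(0.96875, 1),
    protein = c("P1", "P2"),
    protein_positions = list(c(12L, 13L), 7L),
    is_decoy = c(FALSE, TRUE), is_contaminant = c(FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePsmTable(psms, path)
  back <- readPsmTable(path)
  for (col in c("spectrum_id", "peptide", "charge", "psm_probability",
                "protein", "is_decoy", "is_contaminant"))
    expect_identical(back[[col]], psms[[col]])
  expect_identical(as.list(back$mod_positions), as.list(psms$mod_positions))
  expect_identical(as.list(back$protein_positions),
                   as.list(psms$protein_positions))
  expect_equal(as.list(back$ptm_probabilities),
               as.list(psms$ptm_probabilities))
})

test_that("degenerate tables parse or fail with located errors, never crash", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ## header-only file
  writeLines(paste(c("spectrum_id", "peptide", "charge", "mod_positions",
                     "psm_probability", "psm_score", "ptm_probabilities",
                     "protein", "is_decoy", "is_contaminant"),
                   collapse = "\t"), path)
  empty <- readPsmTable(path)
  expect_identical(nrow(empty), 0L)
  ## wrong columns are named in the error
  writeLines("foo\tbar\n1\t2", path)
  expect_error(readPsmTable(path), "lacks required columns")
  ## malformed row is located
  writeLines(c(paste(c("spectrum_id", "peptide", "charge", "mod_positions",
                       "psm_probability", "psm_score", "ptm_probabilities",
                       "protein", "is_decoy", "is_contaminant"),
                     collapse = "\t"),
               "s1\tASK\t2\t9\t0.5\t.\t0.5\tP1\t0\t0"), path)
  expect_error(readPsmTable(path), "row 1.*out of range")
})

test_that("answer keys validate and round-trip", {
  key <- AnswerKey(peptide = c("ASSK", "TPEPK"),
                   truePositions = list(c(2L, 3L), 1L),
                   expectedModCount = c(2L, 1L))
  expect_identical(length(key), 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnswerKey(key, path)
  back <- readAnswerKey(path)
  expect_identical(peptides(back), peptides(key))
  expect_identical(as.list(truePositions(back)), as.list(truePositions(key)))
  expect_identical(expectedModCount(back), expectedModCount(key))
  expect_error(AnswerKey(peptide = "ASK", truePositions = list(9L)),
               "within their peptide")
})

test_that("DecoyConfig enforces the decoy alphabet", {
  expect_identical(decoyResidue(DecoyConfig(decoyResidue = "L")), "L")
  expect_true(is.na(decoyResidue(DecoyConfig())))
  expect_error(DecoyConfig(decoyResidue = "S"), "must be one of")
  expect_error(DecoyConfig(targetResidues = c("S", "S")), "unique")
})
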