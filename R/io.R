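#' @include AllGenerics.R
NULL

.PSM_COLUMNS <- c("spectrum_id", "peptide", "charge", "mod_positions",
                  "psm_probability", "psm_score", "ptm_probabilities",
                  "protein", "is_decoy", "is_contaminant")

.splitInts <- function(x) {
  IRanges::IntegerList(lapply(x, function(v) {
    if (is.na(v) || v == "." || v == "") integer() else
      as.integer(strsplit(v, ";", fixed = TRUE)[[1L]])
  }))
}

.splitNums <- function(x) {
  IRanges::NumericList(lapply(x, function(v) {
    if (is.na(v) || v == "." || v == "") numeric() else
      as.numeric(strsplit(v, ";", fixed = TRUE)[[1L]])
  }))
}

.joinList <- function(x) {
  out <- vapply(as.list(x), function(v) paste(v, collapse = ";"), "")
  out[out == ""] <- "."
  out
}

#' Construct an in-memory PSM table
#'
#' Builds the \linkS4class{DataFrame} representation of peptide-spectrum
#' matches used throughout the package: one row per PSM, with 1-based
#' modification positions (N-terminal residue = position 1) and localization
#' probabilities parallel to them. Probabilities are probabilities of
#' correctness; local error probabilities (PEPs) are derived as one minus
#' probability where needed.
#'
#' @param spectrum_id Character identifiers, one per PSM.
#' @param peptide Uppercase amino acid sequences.
#' @param charge Positive integer precursor charges.
#' @param mod_positions List / \code{IntegerList} of 1-based modified
#'   positions, strictly increasing within each PSM.
#' @param ptm_probabilities List / \code{NumericList} of per-site
#'   localization probabilities, parallel to \code{mod_positions}.
#' @param psm_probability Probability each PSM is correct, \code{NA} when only
#'   a raw score is available (calibrate with \code{\link{calibratePsmTable}}).
#' @param psm_score Optional raw PSM score.
#' @param protein Protein accession (first accession if several).
#' @param protein_positions Optional list of 1-based protein coordinates
#'   parallel to \code{mod_positions}.
#' @param is_decoy Logical, PSM matched a sequence-database decoy protein.
#' @param is_contaminant Logical, PSM matched a contaminant entry.
#' @return A \linkS4class{DataFrame} with one row per PSM.
#' @examples
#' psms <- psmTable(spectrum_id = "s1", peptide = "ASTYK", charge = 2L,
#'                  mod_positions = list(3L), ptm_probabilities = list(0.9),
#'                  psm_probability = 0.99, protein = "P1")
#' validatePsmTable(psms)
#' @export
psmTable <- function(spectrum_id, peptide, charge = 2L,
                     mod_positions, ptm_probabilities,
                     psm_probability = NA_real_, psm_score = NA_real_,
                     protein = NA_character_, protein_positions = NULL,
                     is_decoy = FALSE, is_contaminant = FALSE) {
  n <- length(peptide)
  out <- S4Vectors::DataFrame(
    spectrum_id = as.character(spectrum_id),
    peptide = toupper(as.character(peptide)),
    charge = rep(as.integer(charge), length.out = n),
    mod_positions = IRanges::IntegerList(mod_positions),
    psm_probability = rep(as.numeric(psm_probability), length.out = n),
    psm_score = rep(as.numeric(psm_score), length.out = n),
    ptm_probabilities = IRanges::NumericList(ptm_probabilities),
    protein = rep(as.character(protein), length.out = n),
    is_decoy = rep(as.logical(is_decoy), length.out = n),
    is_contaminant = rep(as.logical(is_contaminant), length.out = n)
  )
  if (!is.null(protein_positions))
    out$protein_positions <- IRanges::IntegerList(protein_positions)
  out
}

#' Validate a PSM table
#'
#' Checks every invariant of the PSM interchange schema and reports each
#' violation with the offending row; the input is never mutated and
#' malformed rows are reported rather than dropped. Row \code{NA} flags
#' table-level problems.
#'
#' Checks: peptides are uppercase amino acid strings; modification positions
#' are within the peptide and strictly increasing; localization probability
#' lists are parallel to position lists; probabilities lie in [0, 1];
#' charges are positive; a missing PSM probability is only allowed when a raw
#' score is present; calibrated and native PSM probabilities are not mixed in
#' one table.
#'
#' @param psms A PSM table as built by \code{\link{psmTable}} or read by
#'   \code{\link{readPsmTable}}.
#' @return A \code{data.frame} with columns \code{row}, \code{field},
#'   \code{message}; zero rows when the table is valid.
#' @export
validatePsmTable <- function(psms) {
  bad <- list()
  note <- function(row, field, message)
    bad[[length(bad) + 1L]] <<- data.frame(row = row, field = field,
                                           message = message)
  miss <- setdiff(.PSM_COLUMNS, colnames(psms))
  if (length(miss)) {
    note(NA_integer_, paste(miss, collapse = ","), "missing required column")
    return(do.call(rbind, bad))
  }
  n <- nrow(psms)
  if (n == 0L)
    return(data.frame(row = integer(), field = character(),
                      message = character()))
  pep <- psms$peptide
  badpep <- which(is.na(pep) | !grepl("^[A-Z]+$", pep))
  for (i in badpep) note(i, "peptide", "not an uppercase amino acid string")
  lens <- nchar(pep)
  mp <- psms$mod_positions
  pp <- psms$ptm_probabilities
  for (i in setdiff(seq_len(n), badpep)) {
    m <- mp[[i]]
    if (length(m)) {
      if (any(m < 1L | m > lens[i]))
        note(i, "mod_positions", "position out of range")
      if (is.unsorted(m, strictly = TRUE))
        note(i, "mod_positions", "positions not strictly increasing")
    }
    if (length(pp[[i]]) != length(m))
      note(i, "ptm_probabilities",
           "length mismatch with mod_positions")
    else if (length(pp[[i]]) && any(pp[[i]] < 0 | pp[[i]] > 1))
      note(i, "ptm_probabilities", "probability outside [0,1]")
  }
  pr <- psms$psm_probability
  for (i in which(!is.na(pr) & (pr < 0 | pr > 1)))
    note(i, "psm_probability", "probability outside [0,1]")
  for (i in which(is.na(pr) & is.na(psms$psm_score)))
    note(i, "psm_probability",
         "missing probability requires a raw score for calibration")
  if (anyNA(pr) && !all(is.na(pr)))
    note(NA_integer_, "psm_probability",
         "table mixes native probabilities with rows needing calibration")
  for (i in which(is.na(psms$charge) | psms$charge < 1L))
    note(i, "charge", "charge must be a positive integer")
  if ("protein_positions" %in% colnames(psms)) {
    ppos <- psms$protein_positions
    for (i in which(lengths(ppos) > 0L & lengths(ppos) != lengths(mp)))
      note(i, "protein_positions", "length mismatch with mod_positions")
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(row = integer(), field = character(), message = character())
}

#' Read / write the PSM interchange table
#'
#' The interchange format is a UTF-8 tab-separated file with a mandatory
#' header and columns \code{spectrum_id}, \code{peptide}, \code{charge},
#' \code{mod_positions} (semicolon-separated 1-based integers),
#' \code{psm_probability}, \code{psm_score}, \code{ptm_probabilities}
#' (semicolon-separated reals parallel to \code{mod_positions}),
#' \code{protein}, \code{is_decoy} (0/1), \code{is_contaminant} (0/1), with
#' \code{"."} for missing values. An optional \code{protein_positions}
#' column (semicolon-separated integers) carries protein coordinates.
#' Native search-engine formats (pepXML, mzIdentML, ...) are deliberately
#' out of scope; export to this schema upstream.
#'
#' @param path File to read or write.
#' @param validate If \code{TRUE} (default) reading stops with a summary of
#'   all violations found by \code{\link{validatePsmTable}}.
#' @return \code{readPsmTable} returns a \linkS4class{DataFrame};
#'   \code{writePsmTable} invisibly returns \code{path}.
#' @export
readPsmTable <- function(path, validate = TRUE) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("."), check.names = FALSE)
  miss <- setdiff(.PSM_COLUMNS, colnames(raw))
  if (length(miss))
    stop("PSM table ", path, " lacks required columns: ",
         paste(miss, collapse = ", "))
  out <- S4Vectors::DataFrame(
    spectrum_id = raw$spectrum_id,
    peptide = raw$peptide,
    charge = as.integer(raw$charge),
    mod_positions = .splitInts(raw$mod_positions),
    psm_probability = as.numeric(raw$psm_probability),
    psm_score = as.numeric(raw$psm_score),
    ptm_probabilities = .splitNums(raw$ptm_probabilities),
    protein = raw$protein,
    is_decoy = raw$is_decoy %in% c("1", "TRUE", "true"),
    is_contaminant = raw$is_contaminant %in% c("1", "TRUE", "true")
  )
  if ("protein_positions" %in% colnames(raw))
    out$protein_positions <- .splitInts(raw$protein_positions)
  if (validate) {
    report <- validatePsmTable(out)
    if (nrow(report))
      stop("invalid PSM table ", path, ":\n",
           paste(sprintf("  row %s, %s: %s",
                         report$row, report$field, report$message),
                 collapse = "\n"))
  }
  out
}

#' @rdname readPsmTable
#' @param psms A PSM table.
#' @export
writePsmTable <- function(psms, path) {
  df <- data.frame(
    spectrum_id = psms$spectrum_id,
    peptide = psms$peptide,
    charge = psms$charge,
    mod_positions = .joinList(psms$mod_positions),
    psm_probability = ifelse(is.na(psms$psm_probability), ".",
                             format(psms$psm_probability, digits = 15)),
    psm_score = ifelse(is.na(psms$psm_score), ".",
                       format(psms$psm_score, digits = 15)),
    ptm_probabilities = .joinList(psms$ptm_probabilities),
    protein = ifelse(is.na(psms$protein), ".", psms$protein),
    is_decoy = as.integer(psms$is_decoy),
    is_contaminant = as.integer(psms$is_contaminant),
    check.names = FALSE
  )
  if ("protein_positions" %in% colnames(psms))
    df$protein_positions <- .joinList(psms$protein_positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an answer key
#'
#' Answer keys are tab-separated files with columns \code{peptide},
#' \code{true_positions} (semicolon-separated 1-based integers) and
#' \code{expected_mod_count}.
#'
#' @param path File to read or write.
#' @return \code{readAnswerKey} returns an \linkS4class{AnswerKey};
#'   \code{writeAnswerKey} invisibly returns \code{path}.
#' @export
readAnswerKey <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("."), check.names = FALSE)
  need <- c("peptide", "true_positions", "expected_mod_count")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("answer key ", path, " lacks columns: ", paste(miss, collapse = ", "))
  AnswerKey(peptide = raw$peptide,
            truePositions = .splitInts(raw$true_positions),
            expectedModCount = as.integer(raw$expected_mod_count))
}

#' @rdname readAnswerKey
#' @param key An \linkS4class{AnswerKey}.
#' @export
writeAnswerKey <- function(key, path) {
  df <- data.frame(peptide = peptides(key),
                   true_positions = .joinList(truePositions(key)),
                   expected_mod_count = expectedModCount(key))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a ranked site table
#'
#' Serializes the site rows (including any estimator and q-value columns) to
#' a tab-separated file; list metadata (ranking key, decoy residue) goes into
#' a commented header line.
#'
#' @param table A \linkS4class{RankedSiteTable}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeSiteTable <- function(table, path) {
  df <- as.data.frame(table)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# phosphoFLR sites: order=%s decoy=%s",
                     orderKey(table),
                     decoyResidue(decoyConfig(table))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
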