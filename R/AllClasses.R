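#' @include phosphoFLR-package.R
NULL

## Residues eligible as decoys: no evidence of phosphorylation (G, L, A),
## plausible-but-undetectable (E), and deliberately poor choices (D, P) kept
## for method-evaluation purposes.
.DECOY_CANDIDATES <- c("A", "G", "L", "D", "E", "P")

setClass("DecoyConfig",
  representation(targetResidues = "character", decoyResidue = "character"),
  prototype(targetResidues = c("S", "T", "Y"), decoyResidue = character())
)

setValidity("DecoyConfig", function(object) {
  msg <- character()
  tr <- object@targetResidues
  dr <- object@decoyResidue
  if (length(tr) < 1L || any(!grepl("^[A-Z]$", tr)))
    msg <- c(msg, "targetResidues must be single uppercase letters")
  if (anyDuplicated(tr))
    msg <- c(msg, "targetResidues must be unique")
  if (length(dr) > 1L)
    msg <- c(msg, "at most one decoy residue is supported")
  if (length(dr) == 1L) {
    if (!dr %in% .DECOY_CANDIDATES)
      msg <- c(msg, sprintf("decoy residue must be one of %s",
                            paste(.DECOY_CANDIDATES, collapse = ", ")))
    if (dr %in% tr)
      msg <- c(msg, "decoy residue must not be a target residue")
  }
  if (length(msg)) msg else TRUE
})

#' Decoy amino acid configuration
#'
#' Pairs the set of genuinely modifiable target residues (S, T and Y for
#' canonical phosphorylation) with the single decoy residue scored as
#' modifiable during the search. Any site reported on the decoy residue is a
#' known false localization. A configuration without a decoy residue
#' (\code{decoyResidue = character()}) is valid and disables the decoy
#' estimator. Eligible decoys are A, G, L, D, E and P: residues never
#' observed phosphorylated (A, G, L), not detectable as phosphorylated under
#' standard enrichment (E), or included as deliberately poor choices for
#' method evaluation (D, P).
#'
#' @param targetResidues Character vector of single uppercase letters that
#'   can genuinely carry the modification. Default \code{c("S","T","Y")}.
#' @param decoyResidue A single letter from A, G, L, D, E, P, or
#'   \code{character()} for no decoy.
#' @return A \code{DecoyConfig} object.
#' @examples
#' cfg <- DecoyConfig(decoyResidue = "A")
#' decoyResidue(cfg)
#' @aliases DecoyConfig-class
#' @export
DecoyConfig <- function(targetResidues = c("S", "T", "Y"),
                        decoyResidue = character()) {
  if (length(decoyResidue) == 1L && is.na(decoyResidue))
    decoyResidue <- character()
  new("DecoyConfig", targetResidues = toupper(targetResidues),
      decoyResidue = toupper(decoyResidue))
}

setClass("FlrCounters",
  representation(targetCount = "numeric", decoyCount = "numeric",
                 nPsm = "integer"),
  prototype(targetCount = 0, decoyCount = 0, nPsm = 0L)
)

setValidity("FlrCounters", function(object) {
  msg <- character()
  if (length(object@targetCount) != 1L || object@targetCount < 0)
    msg <- c(msg, "targetCount must be a single non-negative number")
  if (length(object@decoyCount) != 1L || object@decoyCount < 0)
    msg <- c(msg, "decoyCount must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Residue counters for the decoy FLR estimator
#'
#' Holds the total count of target residues (\eqn{T_c}) and decoy residues
#' (\eqn{X_c}) over the peptide sequences of the retained PSM set, counted
#' with multiplicity (a peptide observed in k PSMs contributes k times).
#' The ratio \eqn{T_c/X_c} converts observed decoy-site counts into the
#' expected number of silent false localizations among target residues.
#' Usually built by \code{\link{countResidues}}.
#'
#' @param targetCount Total target (e.g. S+T+Y) residue count, \eqn{T_c}.
#' @param decoyCount Total decoy residue count, \eqn{X_c}.
#' @param nPsm Number of PSMs the counts were taken over.
#' @return An \code{FlrCounters} object.
#' @aliases FlrCounters-class
#' @export
FlrCounters <- function(targetCount, decoyCount, nPsm = NA_integer_) {
  new("FlrCounters", targetCount = as.numeric(targetCount),
      decoyCount = as.numeric(decoyCount), nPsm = as.integer(nPsm))
}

setClass("AnswerKey",
  representation(peptide = "character", truePositions = "IntegerList",
                 expectedModCount = "integer")
)

setValidity("AnswerKey", function(object) {
  msg <- character()
  n <- length(object@peptide)
  if (length(object@truePositions) != n || length(object@expectedModCount) != n)
    msg <- c(msg, "peptide, truePositions and expectedModCount must be parallel")
  if (anyDuplicated(object@peptide))
    msg <- c(msg, "peptides in an answer key must be unique")
  if (n) {
    lens <- nchar(object@peptide)
    pos <- unlist(object@truePositions, use.names = FALSE)
    lim <- rep(lens, lengths(object@truePositions))
    if (length(pos) && any(pos < 1L | pos > lim))
      msg <- c(msg, "true positions must lie within their peptide")
    if (any(object@expectedModCount < 1L))
      msg <- c(msg, "expectedModCount must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Answer key for synthetic peptide libraries
#'
#' Maps each library peptide to its known true modification positions
#' (1-based, N-terminal residue = 1) and the number of modifications expected
#' on it. Used to compute the answer-key FLR (\code{\link{answerKeyFlr}}) and
#' to filter PSM tables to rows comparable with the key
#' (\code{\link{answerKeyFilter}}).
#'
#' @param peptide Character vector of unique peptide sequences.
#' @param truePositions List (or \linkS4class{IntegerList}) of 1-based true
#'   modified positions, parallel to \code{peptide}.
#' @param expectedModCount Integer vector of expected modification counts;
#'   defaults to the number of true positions per peptide.
#' @return An \code{AnswerKey} object.
#' @examples
#' key <- AnswerKey(peptide = c("ASSK", "TPEPK"),
#'                  truePositions = list(3L, 1L))
#' expectedModCount(key)
#' @aliases AnswerKey-class
#' @export
AnswerKey <- function(peptide, truePositions,
                      expectedModCount = lengths(truePositions)) {
  new("AnswerKey", peptide = as.character(peptide),
      truePositions = IRanges::IntegerList(truePositions),
      expectedModCount = as.integer(expectedModCount))
}

setClass("RankedSiteTable",
  representation(sites = "DataFrame", orderKey = "character",
                 decoyConfig = "DecoyConfig"),
  prototype(orderKey = "combined")
)

.rankColumn <- function(orderKey) {
  switch(orderKey, combined = "combined_probability",
         ptm = "ptm_probability",
         stop("unknown order key: ", orderKey))
}

setValidity("RankedSiteTable", function(object) {
  msg <- character()
  need <- c("peptide", "site_position", "residue", "ptm_probability",
            "is_decoy_site")
  miss <- setdiff(need, colnames(object@sites))
  if (length(miss))
    msg <- c(msg, paste("missing site columns:", paste(miss, collapse = ", ")))
  if (length(object@orderKey) != 1L ||
      !object@orderKey %in% c("combined", "ptm")) {
    msg <- c(msg, "orderKey must be 'combined' or 'ptm'")
  } else if (!length(miss)) {
    ## collapsed tables are ordered by (probability bin, PSM count), not by
    ## the raw key
    keycol <- if ("prob_bin" %in% colnames(object@sites)) "prob_bin" else
      .rankColumn(object@orderKey)
    if (!keycol %in% colnames(object@sites)) {
      msg <- c(msg, paste("missing ranking column", keycol))
    } else {
      key <- object@sites[[keycol]]
      if (anyNA(key))
        msg <- c(msg, "ranking key must not contain NA")
      else if (length(key) > 1L && any(diff(key) > 1e-12))
        msg <- c(msg, "sites must be ordered by non-increasing ranking key")
    }
    for (qc in grep("^q_", colnames(object@sites), value = TRUE)) {
      q <- object@sites[[qc]]
      if (!anyNA(q) && length(q) > 1L && any(diff(q) < -1e-12))
        msg <- c(msg, paste(qc, "must be non-decreasing down the table"))
    }
  }
  if (length(msg)) msg else TRUE
})

setClass("ScoreCalibration",
  representation(breaks = "numeric", pep = "numeric")
)

setValidity("ScoreCalibration", function(object) {
  msg <- character()
  if (length(object@breaks) != length(object@pep) + 1L)
    msg <- c(msg, "breaks must be one longer than pep")
  if (any(object@pep < 0 | object@pep > 1))
    msg <- c(msg, "PEP values must lie in [0, 1]")
  if (length(object@pep) > 1L && any(diff(object@pep) > 1e-12))
    msg <- c(msg, "PEP must be non-increasing with score")
  if (length(msg)) msg else TRUE
})

#' Ranked phosphosite table class
#'
#' S4 container for ranked site observations; see
#' \code{\link{rankSites}} for construction and \code{\link{flrEstimate}}
#' for estimator columns. Collapsed tables (see
#' \code{\link{collapseSites}}) carry \code{prob_bin} and \code{psm_count}
#' columns and are ordered by (probability bin, PSM count) instead of the
#' raw key.
#'
#' @name RankedSiteTable-class
#' @aliases RankedSiteTable
#' @exportClass RankedSiteTable
NULL

#' Histogram score calibration class
#'
#' S4 container for a fitted score-to-probability map; see
#' \code{\link{histogramCalibrate}}.
#'
#' @name ScoreCalibration-class
#' @aliases ScoreCalibration
#' @exportClass ScoreCalibration
NULL

#' @name DecoyConfig-classdef
#' @rdname DecoyConfig
#' @exportClass DecoyConfig
NULL

#' @name FlrCounters-classdef
#' @rdname FlrCounters
#' @exportClass FlrCounters
NULL

#' @name AnswerKey-classdef
#' @rdname AnswerKey
#' @exportClass AnswerKey
NULL
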