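#' @include AllClasses.R
NULL

#' Accessors for phosphoFLR classes
#'
#' Small accessor generics for the package's S4 classes:
#' \code{targetResidues} / \code{decoyResidue} on
#' \linkS4class{DecoyConfig}; \code{targetCount} / \code{decoyCount} on
#' \linkS4class{FlrCounters}; \code{siteData}, \code{orderKey} and
#' \code{decoyConfig} on \linkS4class{RankedSiteTable}; \code{peptides},
#' \code{truePositions} and \code{expectedModCount} on
#' \linkS4class{AnswerKey}.
#'
#' @param x An object of the appropriate class.
#' @return The slot value; \code{siteData} returns the underlying
#'   \linkS4class{DataFrame} of site observations.
#' @name accessors
#' @aliases targetResidues decoyResidue targetCount decoyCount siteData
#'   orderKey decoyConfig peptides truePositions expectedModCount
NULL

#' @rdname accessors
#' @export
setGeneric("targetResidues", function(x) standardGeneric("targetResidues"))
#' @rdname accessors
#' @export
setGeneric("decoyResidue", function(x) standardGeneric("decoyResidue"))
#' @rdname accessors
#' @export
setGeneric("targetCount", function(x) standardGeneric("targetCount"))
#' @rdname accessors
#' @export
setGeneric("decoyCount", function(x) standardGeneric("decoyCount"))
#' @rdname accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))
#' @rdname accessors
#' @export
setGeneric("orderKey", function(x) standardGeneric("orderKey"))
#' @rdname accessors
#' @export
setGeneric("decoyConfig", function(x) standardGeneric("decoyConfig"))
#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setGeneric("truePositions", function(x) standardGeneric("truePositions"))
#' @rdname accessors
#' @export
setGeneric("expectedModCount", function(x) standardGeneric("expectedModCount"))

setMethod("targetResidues", "DecoyConfig", function(x) x@targetResidues)
setMethod("decoyResidue", "DecoyConfig", function(x) {
  if (length(x@decoyResidue)) x@decoyResidue else NA_character_
})
setMethod("targetCount", "FlrCounters", function(x) x@targetCount)
setMethod("decoyCount", "FlrCounters", function(x) x@decoyCount)
setMethod("siteData", "RankedSiteTable", function(x) x@sites)
setMethod("orderKey", "RankedSiteTable", function(x) x@orderKey)
setMethod("decoyConfig", "RankedSiteTable", function(x) x@decoyConfig)
setMethod("peptides", "AnswerKey", function(x) x@peptide)
setMethod("truePositions", "AnswerKey", function(x) x@truePositions)
setMethod("expectedModCount", "AnswerKey", function(x) x@expectedModCount)

#' @describeIn accessors Number of site rows in a ranked table.
#' @export
setMethod("nrow", "RankedSiteTable", function(x) nrow(x@sites))

#' @describeIn accessors Number of peptides in an answer key.
#' @export
setMethod("length", "AnswerKey", function(x) length(x@peptide))

#' Coerce a ranked site table to a data.frame
#'
#' @param x A \linkS4class{RankedSiteTable}.
#' @param row.names,optional Passed on to the \code{DataFrame} method.
#' @param ... Further arguments, ignored.
#' @return A base \code{data.frame} of the site rows.
#' @export
setMethod("as.data.frame", "RankedSiteTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@sites, row.names = row.names, optional = optional, ...)
  })

#' Subset rows of a ranked site table
#'
#' Row subsetting with an increasing index (e.g. \code{head} of the ranked
#' list) preserves the ranking invariant and returns a
#' \linkS4class{RankedSiteTable}.
#'
#' @param x A \linkS4class{RankedSiteTable}.
#' @param i Row index.
#' @param j,drop Ignored; tables are row-subset only.
#' @param ... Ignored.
#' @export
setMethod("[", "RankedSiteTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, sites = x@sites[i, , drop = FALSE])
})

setMethod("show", "DecoyConfig", function(object) {
  dr <- if (length(object@decoyResidue)) object@decoyResidue else "<none>"
  cat("DecoyConfig: targets {",
      paste(object@targetResidues, collapse = ","),
      "}, decoy ", dr, "\n", sep = "")
})

setMethod("show", "FlrCounters", function(object) {
  cat(sprintf("FlrCounters: T_c = %g, X_c = %g (T_c/X_c = %.4g) over %d PSMs\n",
              object@targetCount, object@decoyCount,
              if (object@decoyCount > 0)
                object@targetCount / object@decoyCount else NA_real_,
              object@nPsm))
})

setMethod("show", "AnswerKey", function(object) {
  cat(sprintf("AnswerKey with %d peptides (%d total true sites)\n",
              length(object@peptide),
              sum(lengths(object@truePositions))))
})

setMethod("show", "RankedSiteTable", function(object) {
  n <- nrow(object@sites)
  cat(sprintf("RankedSiteTable with %d site observations, ranked by %s probability\n",
              n, object@orderKey))
  show(object@decoyConfig)
  if (n) {
    cat(sprintf("  decoy-residue sites: %d\n",
                sum(object@sites$is_decoy_site)))
    est <- grep("^flr_", colnames(object@sites), value = TRUE)
    if (length(est))
      cat("  estimators:", paste(sub("^flr_", "", est), collapse = ", "), "\n")
  }
})

setMethod("show", "ScoreCalibration", function(object) {
  cat(sprintf("ScoreCalibration over [%g, %g] with %d bins; PEP range [%g, %g]\n",
              min(object@breaks), max(object@breaks), length(object@pep),
              min(object@pep), max(object@pep)))
})
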