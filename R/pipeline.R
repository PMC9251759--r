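#' @include simulate.R
#' @include calibration.R
#' @include collapse.R
#' @include profiling.R
NULL

#' Run the full FLR pipeline over a PSM table
#'
#' Chains the stages PSM FDR filtering, site expansion, ranking, FLR
#' estimation, collapsing and (optionally) profiling, writing each stage's
#' output as an auditable tab-separated file in \code{outDir} together with
#' a machine-readable provenance record (inputs, parameters, package
#' version). Inputs are never mutated; a failing stage aborts with the stage
#' named.
#'
#' @param input Path to an interchange PSM TSV, or an in-memory PSM table.
#' @param outDir Output directory, created if needed.
#' @param config A \linkS4class{DecoyConfig}.
#' @param fdrAlpha PSM-level FDR threshold; default 0.01.
#' @param mode Ranking mode, \code{"combined"} or \code{"ptm_only"}.
#' @param methods FLR estimators to run (\code{"key"} requires
#'   \code{answerKey}).
#' @param answerKey Optional \linkS4class{AnswerKey} or path to one; when
#'   given, the answer-key comparability filter is applied before ranking.
#' @param collapseBy Collapse grouping key, or \code{NA} to skip collapsing.
#' @param proteins Optional FASTA path or \linkS4class{AAStringSet} for
#'   profiling context; profiling is skipped without it.
#' @param profileAlpha Model-FLR filter for the distance profile; default
#'   0.05.
#' @return Invisibly, a list with the filtered PSMs, the estimated
#'   \linkS4class{RankedSiteTable}, the collapsed table (or \code{NULL}) and
#'   the paths written.
#' @export
runPipeline <- function(input, outDir, config = DecoyConfig(decoyResidue = "A"),
                        fdrAlpha = 0.01, mode = c("combined", "ptm_only"),
                        methods = c("model", "decoy"), answerKey = NULL,
                        collapseBy = "protein_site", proteins = NULL,
                        profileAlpha = 0.05) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  psms <- stage("read", {
    if (is.character(input)) readPsmTable(input) else input
  })
  if (is.character(answerKey))
    answerKey <- stage("read-key", readAnswerKey(answerKey))

  filtered <- stage("psm-fdr", filterPsmFdr(computePsmFdr(psms), fdrAlpha))
  if (!is.null(answerKey))
    filtered <- stage("answer-key-filter",
                      answerKeyFilter(filtered, answerKey))
  paths$psms <- file.path(outDir, "psms.filtered.tsv")
  writePsmTable(filtered, paths$psms)

  ranked <- stage("sites", {
    sites <- expandToSites(filtered, config)
    rankSites(sites, mode = mode, config = config)
  })
  ranked <- stage("estimate", {
    flrEstimate(ranked, methods = methods,
                counters = if ("decoy" %in% methods)
                  countResidues(filtered, config) else NULL,
                key = answerKey, psms = filtered)
  })
  paths$sites <- file.path(outDir, "sites.tsv")
  writeSiteTable(ranked, paths$sites)

  collapsed <- NULL
  if (!is.na(collapseBy)) {
    collapsed <- stage("collapse", collapseSites(ranked, by = collapseBy))
    paths$collapsed <- file.path(outDir, "collapsed.tsv")
    writeSiteTable(collapsed, paths$collapsed)
  }

  if (!is.null(proteins) && "model" %in% methods) {
    prof <- stage("profile", {
      aa <- if (is.character(proteins))
        Biostrings::readAAStringSet(proteins) else proteins
      conf <- thresholdAt(ranked, profileAlpha, method = "model")$subset
      dr <- decoyResidue(config)
      cands <- if (is.na(dr)) targetResidues(config) else dr
      offs <- nearestResidueOffsets(conf, aa, candidates = cands)
      offsSty <- nearestResidueOffsets(conf, aa,
                                       candidates = targetResidues(config))
      both <- rbind(cbind(offsetHistogram(offs), candidate = "decoy"),
                    cbind(offsetHistogram(offsSty), candidate = "target"))
      both
    })
    paths$profile <- file.path(outDir, "profile.tsv")
    utils::write.table(prof, paths$profile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  paths$provenance <- file.path(outDir, "provenance.json")
  jsonlite::write_json(list(
    package = "phosphoFLR",
    version = as.character(utils::packageVersion("phosphoFLR")),
    input = if (is.character(input)) input else "<in-memory>",
    parameters = list(fdr_alpha = fdrAlpha, mode = mode, methods = methods,
                      decoy_residue = decoyResidue(config),
                      collapse_by = collapseBy),
    written = unname(unlist(paths[names(paths) != "provenance"]))
  ), paths$provenance, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(psms = filtered, ranked = ranked, collapsed = collapsed,
                 paths = paths))
}
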