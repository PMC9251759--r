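#' @include io.R
NULL

#' Target-decoy global FDR over PSMs
#'
#' Ranks PSMs by descending probability (or raw score) and computes at every
#' row the raw global FDR as the ratio of cumulative decoy to cumulative
#' target counts, then the q-value as the running minimum of the raw FDR
#' taken from the bottom of the list upward. Ties in the ordering key place
#' decoys above targets (conservative) and are otherwise stable in input
#' order. Contaminant rows count as targets here; they are removed, together
#' with decoys, by \code{filterPsmFdr}.
#'
#' @param psms A PSM table (\code{\link{psmTable}} / \code{\link{readPsmTable}}).
#' @param ordering \code{"probability"} to rank by \code{psm_probability},
#'   \code{"score"} to rank by \code{psm_score}.
#' @param plusOne If \code{TRUE} use the (D+1)/T estimator instead of the
#'   default D/T.
#' @return The input rows, sorted, with added columns \code{rank},
#'   \code{cum_target}, \code{cum_decoy}, \code{fdr_raw} and \code{q_value}.
#' @examples
#' psms <- psmTable(spectrum_id = as.character(1:4),
#'                  peptide = c("ASK", "TSK", "GSK", "YSK"),
#'                  mod_positions = list(2L, 2L, 2L, 2L),
#'                  ptm_probabilities = list(0.9, 0.9, 0.9, 0.9),
#'                  psm_probability = c(0.99, 0.98, 0.97, 0.96),
#'                  is_decoy = c(FALSE, FALSE, TRUE, FALSE))
#' computePsmFdr(psms)$q_value   # 0, 0, 1/2 -> 1/3 after monotonization
#' @export
computePsmFdr <- function(psms, ordering = c("probability", "score"),
                          plusOne = FALSE) {
  ordering <- match.arg(ordering)
  n <- nrow(psms)
  if (n == 0L) {
    out <- psms
    out$rank <- integer()
    out$cum_target <- out$cum_decoy <- integer()
    out$fdr_raw <- out$q_value <- numeric()
    return(out)
  }
  key <- if (ordering == "probability") psms$psm_probability else
    psms$psm_score
  if (anyNA(key))
    stop("every PSM needs a ", ordering, " value to rank by")
  if (all(psms$is_decoy))
    stop("no target PSMs: cannot estimate FDR over an all-decoy table")
  ## descending key; at ties decoys first, then stable input order
  ord <- order(-key, !psms$is_decoy)
  out <- psms[ord, , drop = FALSE]
  cumD <- cumsum(out$is_decoy)
  cumT <- cumsum(!out$is_decoy)
  num <- if (plusOne) cumD + 1L else cumD
  raw <- pmin(1, ifelse(cumT == 0L, 1, num / pmax(cumT, 1L)))
  out$rank <- seq_len(n)
  out$cum_target <- cumT
  out$cum_decoy <- cumD
  out$fdr_raw <- raw
  out$q_value <- rev(cummin(rev(raw)))
  out
}

#' Filter PSMs at a global FDR threshold
#'
#' Keeps target PSMs (decoy and contaminant rows are always removed) whose
#' q-value is at or below \code{alpha}, the stage the paper-style pipeline
#' applies at 1\% before any site-level analysis.
#'
#' @param fdr Output of \code{\link{computePsmFdr}}.
#' @param alpha FDR threshold in (0, 1]; default 0.01.
#' @return A PSM table of retained targets, FDR columns dropped.
#' @export
filterPsmFdr <- function(fdr, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  if (!all(c("q_value", "is_decoy") %in% colnames(fdr)))
    stop("input must come from computePsmFdr()")
  keep <- !fdr$is_decoy & !fdr$is_contaminant & fdr$q_value <= alpha
  out <- fdr[keep, , drop = FALSE]
  out[, setdiff(colnames(out),
                c("rank", "cum_target", "cum_decoy", "fdr_raw", "q_value")),
      drop = FALSE]
}
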