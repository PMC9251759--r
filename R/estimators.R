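#' @include sites.R
NULL

#' Count target and decoy residues over the retained PSM set
#'
#' Computes \eqn{T_c}, the total count of target residues (S, T, Y), and
#' \eqn{X_c}, the total count of decoy residues, over the peptide sequences
#' of all PSMs that contribute at least one scored phosphosite. Counting is
#' per PSM with multiplicity: the same peptide observed in k PSMs contributes
#' its residues k times. A unique-peptide variant is available via
#' \code{uniquePeptides = TRUE}.
#'
#' @param psms The post-FDR PSM table whose sites enter the ranked list.
#' @param config A \linkS4class{DecoyConfig} with a decoy residue set.
#' @param uniquePeptides Count each distinct peptide once instead of once
#'   per PSM.
#' @return An \linkS4class{FlrCounters}.
#' @examples
#' psms <- psmTable(spectrum_id = "s1", peptide = "ASTYAK",
#'                  mod_positions = list(3L), ptm_probabilities = list(0.9),
#'                  psm_probability = 1)
#' countResidues(psms, DecoyConfig(decoyResidue = "A"))  # T_c = 3, X_c = 2
#' @export
countResidues <- function(psms, config, uniquePeptides = FALSE) {
  stopifnot(is(config, "DecoyConfig"))
  dr <- decoyResidue(config)
  if (is.na(dr))
    stop("countResidues needs a decoy residue in the configuration")
  pep <- psms$peptide[lengths(psms$mod_positions) > 0L]
  if (uniquePeptides)
    pep <- unique(pep)
  if (!length(pep))
    stop("no PSMs with a scored phosphosite")
  chars <- strsplit(paste(pep, collapse = ""), "", fixed = TRUE)[[1L]]
  tc <- sum(chars %in% targetResidues(config))
  xc <- sum(chars == dr)
  if (xc == 0L)
    stop("decoy residue ", dr, " absent from data: cannot normalize")
  if (tc == 0L)
    stop("no target residues in the retained PSM set")
  FlrCounters(targetCount = tc, decoyCount = xc, nPsm = length(pep))
}

.siteTable <- function(table) {
  stopifnot(is(table, "RankedSiteTable"))
  table@sites
}

#' Model (probability-sum) global FLR
#'
#' At row n of the ranked list, the model FLR is the running sum of the
#' local error probabilities, \eqn{1 -} combined probability, divided by n:
#' the expected fraction of false localizations among the top n rows if the
#' reported probabilities are well calibrated.
#'
#' @param table A \linkS4class{RankedSiteTable} whose rows carry
#'   \code{combined_probability}.
#' @return Numeric vector of per-row raw model FLR estimates.
#' @examples
#' # probabilities 1, 0.9, 0.8 -> running FLR 0, 0.05, 0.10
#' @export
modelFlr <- function(table) {
  s <- .siteTable(table)
  p <- s$combined_probability
  if (anyNA(p))
    stop("model FLR requires combined_probability on every row")
  cumsum(1 - p) / seq_along(p)
}

#' Decoy amino acid global FLR
#'
#' At row n, the count of phosphorylated decoy residues observed so far,
#' \eqn{\sum_1^n pX_c}, is scaled by the target/decoy residue ratio
#' \eqn{T_c/X_c} to model the silent false localizations expected among
#' target residues, multiplied by 2 to cover false assignments on both the
#' decoy and the target residues, and divided by n:
#' \deqn{FLR(n) = 2 (T_c/X_c) \sum_1^n pX_c / n,} capped at 1. The cap
#' binding before a requested threshold is reported as \code{NA} ("n/a") by
#' \code{\link{thresholdAt}}. The \eqn{\times 2} correction makes the
#' estimator conservative when the decoy residue is rarer than the targets.
#'
#' @param table A \linkS4class{RankedSiteTable} with \code{is_decoy_site}.
#' @param counters \linkS4class{FlrCounters} from \code{\link{countResidues}}.
#' @param excludeDecoyRows Sensitivity-analysis variant: count only
#'   target-residue rows in the denominator \eqn{n}. Default \code{FALSE}:
#'   decoy rows are part of the ranked list being thresholded.
#' @return Numeric vector of per-row raw decoy FLR estimates.
#' @export
decoyFlr <- function(table, counters, excludeDecoyRows = FALSE) {
  stopifnot(is(counters, "FlrCounters"))
  s <- .siteTable(table)
  if (decoyCount(counters) <= 0)
    stop("decoy residue count X_c must be positive")
  ratio <- targetCount(counters) / decoyCount(counters)
  n <- if (excludeDecoyRows) pmax(cumsum(!s$is_decoy_site), 1L) else
    seq_len(nrow(s))
  pmin(1, 2 * ratio * cumsum(s$is_decoy_site) / n)
}

#' Answer-key global FLR
#'
#' For synthetic libraries with known true sites: at row n, the count of
#' sites not matching the answer key, \eqn{F_c}, divided by n. A site is
#' false iff its peptide position is not among the key's true positions for
#' that peptide.
#'
#' @param table A \linkS4class{RankedSiteTable}.
#' @param key An \linkS4class{AnswerKey} covering every peptide in the table
#'   (apply \code{\link{answerKeyFilter}} upstream).
#' @return Numeric vector of per-row raw answer-key FLR estimates.
#' @export
answerKeyFlr <- function(table, key) {
  stopifnot(is(key, "AnswerKey"))
  s <- .siteTable(table)
  m <- match(s$peptide, peptides(key))
  if (anyNA(m))
    stop("peptides missing from answer key: ",
         paste(unique(s$peptide[is.na(m)]), collapse = ", "))
  truth <- truePositions(key)
  false <- !mapply(function(i, pos) pos %in% truth[[i]], m, s$site_position)
  cumsum(false) / seq_along(false)
}

#' Filter PSMs for comparability with an answer key
#'
#' Retains only PSMs whose peptide is a full-length answer-key entry and
#' whose reported modification count equals the key's expected count.
#' Partial peptides (proper substrings of a key peptide) and peptides absent
#' from the key are removed, as are rows flagged as carrying additional
#' variable modifications (optional logical column \code{has_other_mods}).
#' Removals are recorded, with reasons, in
#' \code{metadata(result)$removals}.
#'
#' @param psms A PSM table.
#' @param key An \linkS4class{AnswerKey}.
#' @return The retained PSM rows; inspect
#'   \code{S4Vectors::metadata(result)$removals} for what was dropped.
#' @export
answerKeyFilter <- function(psms, key) {
  stopifnot(is(key, "AnswerKey"))
  kp <- peptides(key)
  m <- match(psms$peptide, kp)
  reason <- rep(NA_character_, nrow(psms))
  inkey <- !is.na(m)
  partial <- !inkey & vapply(psms$peptide, function(p)
    any(grepl(p, kp, fixed = TRUE)), logical(1))
  reason[partial] <- "partial peptide"
  reason[!inkey & !partial] <- "not in key"
  cnt <- lengths(psms$mod_positions)
  mism <- inkey & cnt != expectedModCount(key)[m]
  reason[mism] <- "count mismatch"
  if ("has_other_mods" %in% colnames(psms)) {
    om <- inkey & !mism & psms$has_other_mods %in% TRUE
    reason[om] <- "additional modifications"
  }
  keep <- is.na(reason)
  out <- psms[keep, , drop = FALSE]
  S4Vectors::metadata(out)$removals <-
    data.frame(row = which(!keep), peptide = psms$peptide[!keep],
               reason = reason[!keep])
  out
}

#' Monotonize raw FLR estimates into q-values
#'
#' The q-value at row n is the minimum raw FLR at or below that row:
#' \code{q(n) = min(raw(m), m >= n)}, computed as a running minimum from the
#' bottom of the ranked list upward. q-values are non-decreasing down the
#' list and never exceed the raw estimate.
#'
#' @param raw Numeric vector of per-row raw FLR values in [0, 1].
#' @return Numeric vector of q-values.
#' @examples
#' toQValues(c(0, 0.2, 0.1))  # 0, 0.1, 0.1
#' @export
toQValues <- function(raw) {
  if (length(raw) && (anyNA(raw) || any(raw < 0 | raw > 1)))
    stop("raw FLR values must lie in [0, 1]")
  rev(cummin(rev(raw)))
}

#' Attach FLR estimators and q-values to a ranked table
#'
#' Runs the requested estimators over a ranked site table and appends, per
#' estimator \code{m}, a raw column \code{flr_m} and a monotonized column
#' \code{q_m}. The decoy estimator needs residue counters; the answer-key
#' estimator needs an answer key.
#'
#' @param table A \linkS4class{RankedSiteTable}.
#' @param methods Subset of \code{c("model", "decoy", "key")}.
#' @param counters \linkS4class{FlrCounters}; computed with
#'   \code{\link{countResidues}} on \code{psms} when omitted.
#' @param key \linkS4class{AnswerKey} for the answer-key estimator.
#' @param psms Post-FDR PSM table, used only to derive \code{counters}.
#' @return The table with estimator columns added.
#' @export
flrEstimate <- function(table, methods = c("model", "decoy"),
                        counters = NULL, key = NULL, psms = NULL) {
  methods <- match.arg(methods, c("model", "decoy", "key"),
                       several.ok = TRUE)
  s <- .siteTable(table)
  if ("model" %in% methods) {
    s$flr_model <- modelFlr(table)
    s$q_model <- toQValues(s$flr_model)
  }
  if ("decoy" %in% methods) {
    if (is.null(counters)) {
      if (is.null(psms))
        stop("decoy estimator needs counters= or psms= to count residues")
      counters <- countResidues(psms, decoyConfig(table))
    }
    s$flr_decoy <- decoyFlr(table, counters)
    s$q_decoy <- toQValues(s$flr_decoy)
  }
  if ("key" %in% methods) {
    if (is.null(key))
      stop("answer-key estimator needs key=")
    s$flr_key <- answerKeyFlr(table, key)
    s$q_key <- toQValues(s$flr_key)
  }
  initialize(table, sites = s)
}

#' Threshold a ranked table at a global FLR
#'
#' Returns all rows down to the last row whose q-value for the chosen
#' estimator is at or below \code{alpha}, together with the count of
#' target-residue sites among them (the usual sensitivity measure). When
#' the estimator is pinned at its cap of 1 before \code{alpha} is reached,
#' the threshold is unattainable and the count is reported as \code{NA}.
#'
#' @param table A \linkS4class{RankedSiteTable} carrying \code{q_<method>}.
#' @param alpha Global FLR threshold in (0, 1].
#' @param method Which estimator's q-values to threshold on.
#' @return A list with \code{n_rows}, \code{n_target_sites} and
#'   \code{subset} (a \linkS4class{RankedSiteTable} of accepted rows).
#' @export
thresholdAt <- function(table, alpha, method = c("decoy", "model", "key")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  s <- .siteTable(table)
  qc <- paste0("q_", method)
  if (!qc %in% colnames(s))
    stop("column ", qc, " absent: run flrEstimate() first")
  q <- s[[qc]]
  ok <- which(q <= alpha)
  if (!length(ok))
    return(list(n_rows = 0L, n_target_sites = if (all(q >= 1)) NA_integer_
                else 0L,
                subset = table[integer(0)]))
  last <- max(ok)
  sub <- table[seq_len(last)]
  list(n_rows = last,
       n_target_sites = sum(!s$is_decoy_site[seq_len(last)]),
       subset = sub)
}
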