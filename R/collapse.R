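#' @include estimators.R
NULL

#' Collapse multi-PSM observations of a site to single rows
#'
#' Reduces a ranked site table to one row per site (or per peptidoform),
#' balancing maximum probability against spectral support: each group keeps
#' the maximum ranking probability across its PSMs, that maximum is binned
#' to two decimal places (floor, so 0.9999 stays in bin 0.99), and rows are
#' ordered by bin descending, then by the count of supporting PSMs
#' descending. This ranks a site seen in many PSMs above a slightly
#' higher-scoring site seen once within the same probability bin, reflecting
#' that high-scoring single-PSM hits are enriched for decoys. Remaining ties
#' break on the unbinned maximum, then keep ranked order. Decoy flags
#' survive collapse, so the decoy FLR can be recomputed on the collapsed
#' table using the pre-collapse residue counters; the model estimator's
#' calibration assumptions do not hold after collapse and no probability
#' combination across PSMs is attempted.
#'
#' @param table A \linkS4class{RankedSiteTable}.
#' @param by Grouping key: \code{"protein_site"} (protein accession +
#'   protein coordinate; requires protein positions) or
#'   \code{"peptidoform"} (peptide sequence + peptide position).
#' @return A \linkS4class{RankedSiteTable} with one row per group and added
#'   columns \code{psm_count} and \code{prob_bin}.
#' @examples
#' # a 0.912 site with 7 PSMs outranks a 0.914 site with 1 PSM: both bin
#' # to 0.91 and the PSM count decides
#' @export
collapseSites <- function(table, by = c("protein_site", "peptidoform")) {
  by <- match.arg(by)
  s <- .siteTable(table)
  if (by == "protein_site") {
    if (!"protein_position" %in% colnames(s) || anyNA(s$protein_position))
      stop("protein_site collapse requires protein coordinates on every row")
    grp <- paste0(s$protein, "@", s$protein_position)
  } else {
    grp <- paste0(s$peptide, "@", s$site_position)
  }
  keycol <- .rankColumn(orderKey(table))
  ## table is ranked, so the first row of each group attains the group max
  first <- !duplicated(grp)
  out <- s[first, , drop = FALSE]
  gid <- match(grp, grp[first])
  out$psm_count <- tabulate(gid, nbins = sum(first))
  maxp <- out[[keycol]]
  ## floor to 2 decimals; epsilon guards against 0.29 * 100 = 28.999...
  out$prob_bin <- floor(maxp * 100 + 1e-9) / 100
  ord <- order(-out$prob_bin, -out$psm_count, -maxp)
  out <- out[ord, , drop = FALSE]
  drop <- grep("^(flr|q)_", colnames(out))
  if (length(drop)) out <- out[, -drop, drop = FALSE]
  initialize(table, sites = out)
}
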