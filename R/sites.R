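#' @include psmFdr.R
NULL

#' Expand PSMs into one row per scored phosphosite
#'
#' Converts an FDR-filtered PSM table into a site-based table: one row per
#' (PSM, modification position), carrying the localization probability for
#' that site, the combined probability (PSM probability times localization
#' probability), and a flag for sites falling on the configured decoy
#' residue. Decoy-protein and contaminant PSMs should have been removed by
#' \code{\link{filterPsmFdr}} beforehand.
#'
#' @param psms A PSM table; \code{ptm_probabilities} must be parallel to
#'   \code{mod_positions} in every row.
#' @param config A \linkS4class{DecoyConfig}.
#' @return A \linkS4class{DataFrame} with one row per site: columns
#'   \code{spectrum_id}, \code{peptide}, \code{charge}, \code{site_position},
#'   \code{residue}, \code{psm_probability}, \code{ptm_probability},
#'   \code{combined_probability}, \code{is_decoy_site}, \code{protein},
#'   \code{protein_position} (\code{NA} when unknown) and \code{psm_index}
#'   (row of the source PSM).
#' @examples
#' psms <- psmTable(spectrum_id = "s1", peptide = "ASTYK",
#'                  mod_positions = list(c(2L, 3L)),
#'                  ptm_probabilities = list(c(0.8, 0.6)),
#'                  psm_probability = 0.9)
#' expandToSites(psms, DecoyConfig(decoyResidue = "A"))
#' @export
expandToSites <- function(psms, config = DecoyConfig()) {
  stopifnot(is(config, "DecoyConfig"))
  nmod <- lengths(psms$mod_positions)
  bad <- which(lengths(psms$ptm_probabilities) != nmod)
  if (length(bad))
    stop("ptm_probabilities length mismatch with mod_positions in row(s) ",
         paste(bad, collapse = ", "))
  idx <- rep(seq_len(nrow(psms)), nmod)
  pos <- unlist(psms$mod_positions, use.names = FALSE)
  ptm <- unlist(psms$ptm_probabilities, use.names = FALSE)
  res <- substring(psms$peptide[idx], pos, pos)
  ppos <- if ("protein_positions" %in% colnames(psms) &&
              all(lengths(psms$protein_positions) == nmod))
    unlist(psms$protein_positions, use.names = FALSE)
  else rep(NA_integer_, length(idx))
  dr <- decoyResidue(config)
  S4Vectors::DataFrame(
    spectrum_id = psms$spectrum_id[idx],
    peptide = psms$peptide[idx],
    charge = psms$charge[idx],
    site_position = pos,
    residue = res,
    psm_probability = psms$psm_probability[idx],
    ptm_probability = ptm,
    combined_probability = psms$psm_probability[idx] * ptm,
    is_decoy_site = !is.na(dr) & res == dr,
    protein = psms$protein[idx],
    protein_position = ppos,
    psm_index = idx
  )
}

#' Rank site observations into a RankedSiteTable
#'
#' Sorts site rows in descending order of the combined probability (default)
#' or of the localization probability alone -- the latter matches the
#' synthetic-library analyses where the search database is too small for the
#' PSM probability to be well estimated. At equal keys, decoy-residue sites
#' sort above target sites (conservative for every downstream estimator);
#' remaining ties keep input order. Ranking changes only the order of rows,
#' never their multiset.
#'
#' @param sites Output of \code{\link{expandToSites}}.
#' @param mode \code{"combined"} or \code{"ptm_only"}.
#' @param config The \linkS4class{DecoyConfig} the sites were built under.
#' @return A \linkS4class{RankedSiteTable}.
#' @export
rankSites <- function(sites, mode = c("combined", "ptm_only"),
                      config = DecoyConfig()) {
  mode <- match.arg(mode)
  orderKey <- if (mode == "combined") "combined" else "ptm"
  key <- if (orderKey == "combined") sites$combined_probability else
    sites$ptm_probability
  if (anyNA(key))
    stop(if (orderKey == "combined")
      "mode 'combined' requires psm_probability on every row" else
      "ptm_probability missing on some rows")
  ord <- order(-key, !sites$is_decoy_site)
  new("RankedSiteTable", sites = sites[ord, , drop = FALSE],
      orderKey = orderKey, decoyConfig = config)
}
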