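#' @include estimators.R
NULL

#' Signed offset to the nearest candidate residue around confident sites
#'
#' For each assumed-correct phosphosite, finds the signed offset (negative =
#' toward the N-terminus) of the nearest residue from a candidate set within
#' a window, excluding the site's own position. Comparing the offset
#' distribution for a prospective decoy residue with the distribution for
#' S/T/Y around the same sites is the package's first decoy-suitability
#' diagnostic: a good decoy should sit at distances from true sites similar
#' to those of genuine target residues, since incorrect localizations fall
#' preferentially on nearby residues. Pass sites already filtered to an
#' assumed-correct subset (e.g. 5\% model FLR).
#'
#' Distances are measured on the protein sequence when protein coordinates
#' and sequences are available, otherwise on the peptide with a warning.
#' Equidistant candidates on both sides resolve to the negative (N-terminal)
#' offset.
#'
#' @param sites A \linkS4class{RankedSiteTable} (or its \code{DataFrame}) of
#'   confident sites.
#' @param proteins An \linkS4class{AAStringSet} of protein sequences named
#'   by accession, or \code{NULL} to use peptide context.
#' @param candidates Character vector of residues to search for.
#' @param window Maximum absolute offset considered; default 10.
#' @return Integer vector of signed offsets, \code{NA} where no candidate
#'   lies within the window.
#' @examples
#' # protein MASPK, site S at 3: nearest A is at offset -1
#' @export
nearestResidueOffsets <- function(sites, proteins = NULL, candidates,
                                  window = 10L) {
  s <- if (is(sites, "RankedSiteTable")) siteData(sites) else sites
  stopifnot(length(candidates) >= 1L, window >= 1L)
  useProtein <- !is.null(proteins) && "protein_position" %in% colnames(s) &&
    !anyNA(s$protein_position)
  if (!useProtein && !is.null(proteins))
    warning("protein coordinates incomplete; falling back to peptide context")
  if (useProtein) {
    seqs <- as.character(proteins)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ctx <- seqs[s$protein]
    if (anyNA(ctx))
      stop("proteins missing from context: ",
           paste(unique(s$protein[is.na(ctx)]), collapse = ", "))
    pos <- s$protein_position
  } else {
    if (is.null(proteins))
      warning("no protein context supplied; using peptide context")
    ctx <- s$peptide
    pos <- s$site_position
  }
  bad <- which(pos < 1L | pos > nchar(ctx))
  if (length(bad))
    stop("site position outside its context sequence for record(s) ",
         paste(s$spectrum_id[bad], collapse = ", "))
  offs <- c(as.vector(rbind(-seq_len(window), seq_len(window))))  # -1,1,-2,2,...
  vapply(seq_along(ctx), function(i) {
    sq <- ctx[[i]]
    L <- nchar(sq)
    for (d in offs) {
      p <- pos[i] + d
      if (p >= 1L && p <= L &&
          substring(sq, p, p) %in% candidates)
        return(d)
    }
    NA_integer_
  }, integer(1))
}

#' Normalized offset histogram
#'
#' Tabulates signed nearest-residue offsets into normalized frequencies
#' (summing to one over the reported offsets). \code{NA} offsets -- sites
#' with no candidate in the window -- are excluded.
#'
#' @param offsets Integer offsets from \code{\link{nearestResidueOffsets}}.
#' @return A \code{data.frame} with columns \code{offset} and
#'   \code{frequency}.
#' @export
offsetHistogram <- function(offsets) {
  offsets <- offsets[!is.na(offsets)]
  if (!length(offsets))
    stop("no offsets to histogram")
  tab <- table(offsets)
  data.frame(offset = as.integer(names(tab)),
             frequency = as.numeric(tab) / sum(tab))
}

#' Mean site probability by flanking amino acid
#'
#' The second decoy-suitability diagnostic: among assumed-correct sites
#' (combined probability at or above \code{minProbability}, default 0.68 --
#' the average minimum combined probability at a 5\% decoy-FLR cutoff),
#' computes the mean combined probability grouped by the amino acid at a
#' fixed offset (-1 or +1) from the site. A decoy residue whose presence
#' next to a site systematically depresses localization probabilities (as
#' glycine before phosphoserine does) is a poor choice, inflating its FLR
#' estimate. Sites whose peptide lacks the neighbor position are skipped.
#'
#' @param sites A \linkS4class{RankedSiteTable} or site \code{DataFrame}.
#' @param offset \code{-1} (N-terminal neighbor) or \code{+1}.
#' @param minProbability Combined-probability filter; default 0.68.
#' @return A \code{data.frame} with columns \code{residue},
#'   \code{mean_probability} and \code{n_sites}.
#' @export
proximalProbabilityProfile <- function(sites, offset = -1L,
                                       minProbability = 0.68) {
  stopifnot(offset %in% c(-1L, 1L))
  s <- if (is(sites, "RankedSiteTable")) siteData(sites) else sites
  keep <- !is.na(s$combined_probability) &
    s$combined_probability >= minProbability
  s <- s[keep, , drop = FALSE]
  npos <- s$site_position + offset
  inside <- npos >= 1L & npos <= nchar(s$peptide)
  s <- s[inside, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(residue = character(), mean_probability = numeric(),
                      n_sites = integer()))
  neigh <- substring(s$peptide, npos[inside], npos[inside])
  agg <- aggregate(s$combined_probability, by = list(residue = neigh),
                   FUN = mean)
  cnt <- as.data.frame(table(neigh), stringsAsFactors = FALSE)
  out <- data.frame(residue = agg$residue, mean_probability = agg$x,
                    n_sites = cnt$Freq[match(agg$residue, cnt$neigh)])
  out[order(out$residue), , drop = FALSE]
}
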