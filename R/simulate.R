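#' @include decoyDatabase.R
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Tryptic-like digestion: cut after K/R unless followed by P; fragments are
## combined up to `missed` missed cleavages. Returns start/end coordinates.
.digest <- function(chars, missed = 2L) {
  n <- length(chars)
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut == n | chars[pmin(cut + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut, n))
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  nf <- length(starts)
  out <- list()
  for (mc in 0:missed) {
    i <- seq_len(nf - mc)
    if (!length(i)) break
    out[[mc + 1L]] <- cbind(start = starts[i], end = ends[i + mc])
  }
  do.call(rbind, out)
}

#' Simulate site-level search output with known ground truth
#'
#' Generates the statistical structure the FLR estimators assume, at the
#' probability level (no spectra): random proteins with configurable residue
#' frequencies are digested into tryptic-like peptides (cut after K/R, not
#' before P, up to \code{missedCleavages} missed cleavages, length clamped
#' to \code{peptideLengthRange}); each usable peptide carries one true
#' phosphosite on a target residue; PSMs sample peptides with replacement.
#' Per PSM a localization probability is drawn from
#' \code{Beta(correctnessShape)} and a PSM probability from
#' \code{Beta(psmShape)}; the row is correct when independent Bernoulli
#' draws at both probabilities succeed, so the probability a row is correct
#' equals its combined probability. Incorrect rows are relocated onto a
#' candidate residue (target or decoy) of the peptide other than the true
#' site, uniformly (\code{mislocalization = "uniform"}) or with weight
#' proportional to 1/distance (\code{"nearest"}). \code{motifBias > 1}
#' multiplies the relocation weight of a decoy residue sitting immediately
#' N-terminal of the true site, emulating motif-driven confusion such as
#' Gly-Ser. Reported probabilities equal the generative ones in
#' \code{"calibrated"} mode or are shifted on the logit scale by
#' \code{miscalibrationShift} in \code{"miscalibrated"} mode.
#'
#' Usable peptides must contain at least one target residue and at least two
#' candidate residues, so every incorrect row has somewhere to land.
#'
#' @param nPsms Number of PSM rows to emit.
#' @param nProteins Number of synthetic proteins.
#' @param proteinLengthMean Mean protein length (gamma-distributed, floor 50).
#' @param residueFrequencies Named numeric vector of amino acid frequencies
#'   over the 20-letter alphabet; default uniform. Need not be normalized.
#' @param config \linkS4class{DecoyConfig}; the decoy residue must have
#'   positive frequency.
#' @param correctnessShape Beta shape parameters for localization
#'   probabilities; default \code{c(8, 1)} (right-skewed, confident sites).
#' @param psmShape Beta shape parameters for PSM probabilities; default
#'   \code{c(99, 1)}, emulating a 1\% FDR-filtered PSM list.
#' @param mislocalization \code{"uniform"} or \code{"nearest"}.
#' @param calibration \code{"calibrated"} or \code{"miscalibrated"}.
#' @param miscalibrationShift Logit-scale shift applied to reported
#'   probabilities in miscalibrated mode.
#' @param motifBias Relocation weight multiplier for a decoy residue at
#'   position (true site - 1); 1 disables the bias.
#' @param missedCleavages Maximum missed cleavages; default 2.
#' @param peptideLengthRange Inclusive peptide length bounds; default 7-30.
#' @param seed Mandatory integer seed; the same seed reproduces the output
#'   exactly.
#' @return A list with elements \code{psms} (PSM table, one phosphosite per
#'   row), \code{answerKey} (\linkS4class{AnswerKey} over the sampled
#'   peptides), \code{truth} (\linkS4class{DataFrame}: per-row
#'   \code{is_correct}, true and reported positions and residues), and
#'   \code{proteins} (\linkS4class{AAStringSet}).
#' @examples
#' sim <- simulateSites(nPsms = 200, nProteins = 30, seed = 1)
#' mean(sim$truth$is_correct)
#' @export
simulateSites <- function(nPsms = 5000L, nProteins = 500L,
                          proteinLengthMean = 350,
                          residueFrequencies = NULL,
                          config = DecoyConfig(decoyResidue = "A"),
                          correctnessShape = c(8, 1),
                          psmShape = c(99, 1),
                          mislocalization = c("uniform", "nearest"),
                          calibration = c("calibrated", "miscalibrated"),
                          miscalibrationShift = 0,
                          motifBias = 1,
                          missedCleavages = 2L,
                          peptideLengthRange = c(7L, 30L),
                          seed) {
  mislocalization <- match.arg(mislocalization)
  calibration <- match.arg(calibration)
  if (missing(seed))
    stop("a seed is mandatory for reproducible simulation")
  stopifnot(is(config, "DecoyConfig"))
  dr <- decoyResidue(config)
  if (is.na(dr))
    stop("simulation requires a decoy residue in the configuration")
  if (is.null(residueFrequencies))
    residueFrequencies <- setNames(rep(1 / 20, 20), .AA20)
  freq <- setNames(rep(0, 20), .AA20)
  freq[names(residueFrequencies)] <- residueFrequencies
  freq <- freq / sum(freq)
  if (freq[dr] <= 0)
    stop("decoy residue ", dr, " absent from residue frequencies")
  if (sum(freq[targetResidues(config)]) <= 0)
    stop("target residues absent from residue frequencies")

  .withSeed(seed, {
    ## --- proteins -------------------------------------------------------
    plen <- pmax(50L, round(rgamma(nProteins, shape = 4,
                                   scale = proteinLengthMean / 4)))
    protChars <- lapply(plen, function(L)
      sample(.AA20, L, replace = TRUE, prob = freq))
    protSeq <- vapply(protChars, paste, "", collapse = "")
    accession <- sprintf("SYNPROT%04d", seq_len(nProteins))
    proteins <- Biostrings::AAStringSet(setNames(protSeq, accession))

    ## --- peptide pool ---------------------------------------------------
    cand_alpha <- c(targetResidues(config), dr)
    pool <- list()
    for (i in seq_len(nProteins)) {
      fr <- .digest(protChars[[i]], missed = missedCleavages)
      len <- fr[, "end"] - fr[, "start"] + 1L
      fr <- fr[len >= peptideLengthRange[1] & len <= peptideLengthRange[2], ,
               drop = FALSE]
      if (!nrow(fr)) next
      pool[[length(pool) + 1L]] <- data.frame(
        protein = accession[i], start = fr[, "start"],
        peptide = substring(protSeq[i], fr[, "start"], fr[, "end"]))
    }
    if (!length(pool))
      stop("digestion produced no peptides in the length range")
    pool <- do.call(rbind, pool)
    pool <- pool[!duplicated(pool$peptide), , drop = FALSE]
    pepChars <- strsplit(pool$peptide, "", fixed = TRUE)
    candPos <- lapply(pepChars, function(ch) which(ch %in% cand_alpha))
    targPos <- lapply(pepChars, function(ch)
      which(ch %in% targetResidues(config)))
    usable <- lengths(targPos) >= 1L & lengths(candPos) >= 2L
    pool <- pool[usable, , drop = FALSE]
    pepChars <- pepChars[usable]
    candPos <- candPos[usable]
    targPos <- targPos[usable]
    npep <- nrow(pool)
    if (!npep)
      stop("no usable peptides (need >=1 target and >=2 candidate residues)")
    ## one fixed true site per peptide, so the answer key is unambiguous
    trueSite <- vapply(targPos, function(p)
      if (length(p) == 1L) p else sample(p, 1L), integer(1))

    ## --- PSM rows -------------------------------------------------------
    pick <- sample.int(npep, nPsms, replace = TRUE)
    pPtm <- rbeta(nPsms, correctnessShape[1], correctnessShape[2])
    pPsm <- rbeta(nPsms, psmShape[1], psmShape[2])
    okPtm <- runif(nPsms) < pPtm
    okPsm <- runif(nPsms) < pPsm
    correct <- okPtm & okPsm
    reported <- integer(nPsms)
    for (j in seq_len(nPsms)) {
      i <- pick[j]
      ts <- trueSite[i]
      if (correct[j]) {
        reported[j] <- ts
      } else {
        cand <- setdiff(candPos[[i]], ts)
        w <- if (mislocalization == "nearest") 1 / abs(cand - ts) else
          rep(1, length(cand))
        if (motifBias != 1) {
          hit <- cand == ts - 1L & pepChars[[i]][cand] == dr
          w[hit] <- w[hit] * motifBias
        }
        reported[j] <- if (length(cand) == 1L) cand else
          sample(cand, 1L, prob = w)
      }
    }
    repPtm <- pPtm
    repPsm <- pPsm
    if (calibration == "miscalibrated") {
      repPtm <- plogis(qlogis(pPtm) + miscalibrationShift)
      repPsm <- plogis(qlogis(pPsm) + miscalibrationShift)
    }
    residue <- substring(pool$peptide[pick], reported, reported)

    psms <- psmTable(
      spectrum_id = sprintf("PSM%06d", seq_len(nPsms)),
      peptide = pool$peptide[pick],
      charge = sample(2:3, nPsms, replace = TRUE),
      mod_positions = as.list(reported),
      ptm_probabilities = as.list(repPtm),
      psm_probability = repPsm,
      protein = pool$protein[pick],
      protein_positions = as.list(pool$start[pick] + reported - 1L)
    )
    usedPep <- sort(unique(pick))
    key <- AnswerKey(peptide = pool$peptide[usedPep],
                     truePositions = as.list(trueSite[usedPep]),
                     expectedModCount = rep(1L, length(usedPep)))
    truth <- S4Vectors::DataFrame(
      spectrum_id = psms$spectrum_id,
      peptide = psms$peptide,
      true_position = trueSite[pick],
      reported_position = reported,
      reported_residue = residue,
      is_correct = correct
    )
    list(psms = psms, answerKey = key, truth = truth, proteins = proteins)
  })
}

#' True per-row FLR from simulation ground truth
#'
#' Computes the running fraction of incorrect rows down a ranked site table,
#' using the simulator's per-row correctness labels. This is the quantity
#' the model, decoy and answer-key estimators are trying to recover.
#'
#' @param table A \linkS4class{RankedSiteTable} built from simulated PSMs.
#' @param truth The \code{truth} component of \code{\link{simulateSites}}.
#' @return Numeric vector of per-row true FLR values.
#' @export
trueFlr <- function(table, truth) {
  s <- .siteTable(table)
  m <- match(paste(s$spectrum_id, s$site_position),
             paste(truth$spectrum_id, truth$reported_position))
  if (anyNA(m))
    stop("table rows are not aligned with the simulation truth")
  cumsum(!truth$is_correct[m]) / seq_along(m)
}
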