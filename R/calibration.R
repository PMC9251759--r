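#' @include estimators.R
NULL

## Weighted pool-adjacent-violators: smallest-squares non-increasing fit of
## y against index, with weights w. Used to keep per-bin PEPs monotone.
.pavaDecreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  ## fit non-decreasing on reversed vector, then reverse back
  y <- rev(y); w <- rev(w)
  vals <- numeric(n); wts <- numeric(n); idx <- integer(n); k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    vals[k] <- y[i]; wts[k] <- w[i]; idx[k] <- 1L
    while (k > 1L && vals[k - 1L] > vals[k]) {
      tw <- wts[k - 1L] + wts[k]
      vals[k - 1L] <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) / tw
      wts[k - 1L] <- tw
      idx[k - 1L] <- idx[k - 1L] + idx[k]
      k <- k - 1L
    }
  }
  rev(rep(vals[seq_len(k)], idx[seq_len(k)]))
}

#' Calibrate raw scores into probabilities by target/decoy histogram binning
#'
#' Mirrors the handling of engines that report raw scores rather than
#' probabilities: scores of targets and decoys are binned into equal-width
#' histogram bins over the observed range; each bin's posterior error
#' probability is estimated as \code{min(1, D_b / T_b)} from its decoy and
#' target counts; bins without targets inherit the PEP of the nearest
#' populated bin; and the per-bin PEPs are made monotone non-increasing in
#' score by weighted pool-adjacent-violators so that the returned
#' probability, \code{1 - PEP}, never decreases with score.
#'
#' @param score Numeric vector of finite raw scores.
#' @param isDecoy Logical vector parallel to \code{score}.
#' @param bins Number of equal-width bins; default 100.
#' @return A \linkS4class{ScoreCalibration}; apply it with
#'   \code{\link{calibrateScores}}.
#' @examples
#' cal <- histogramCalibrate(c(rnorm(200, 3), rnorm(200, 0)),
#'                           rep(c(FALSE, TRUE), each = 200), bins = 20)
#' calibrateScores(cal, c(-1, 3.5))
#' @export
histogramCalibrate <- function(score, isDecoy, bins = 100L) {
  stopifnot(length(score) == length(isDecoy), bins >= 1L)
  if (any(!is.finite(score)))
    stop("scores must be finite")
  if (!any(isDecoy))
    stop("cannot calibrate without decoys")
  if (all(isDecoy))
    stop("cannot calibrate without targets")
  rng <- range(score)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(score, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tb <- tabulate(bin[!isDecoy], nbins = bins)
  db <- tabulate(bin[isDecoy], nbins = bins)
  pep <- ifelse(tb > 0L, pmin(1, db / pmax(tb, 1L)), NA_real_)
  ## zero-target bins inherit the nearest populated bin (ties: lower score,
  ## i.e. the more conservative side)
  pop <- which(!is.na(pep))
  if (!length(pop)) stop("no populated target bins")
  for (b in which(is.na(pep))) {
    nearest <- pop[which.min(abs(pop - b))]
    pep[b] <- pep[nearest]
  }
  w <- pmax(tb + db, 1L)
  new("ScoreCalibration", breaks = breaks,
      pep = pmin(1, pmax(0, .pavaDecreasing(pep, w))))
}

#' Apply a score calibration
#'
#' Maps scores to estimated probabilities of correctness, \code{1 - PEP} of
#' the score's histogram bin; scores outside the fitted range clamp to the
#' first/last bin.
#'
#' @param calibration A \linkS4class{ScoreCalibration}.
#' @param score Numeric scores to convert.
#' @return Probabilities in [0, 1], monotone non-decreasing in score.
#' @export
calibrateScores <- function(calibration, score) {
  stopifnot(is(calibration, "ScoreCalibration"))
  bin <- findInterval(score, calibration@breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  1 - calibration@pep[bin]
}

#' Fill PSM or site probabilities from raw scores
#'
#' Convenience wrapper fitting \code{\link{histogramCalibrate}} on a PSM
#' table's raw scores (targets and decoys pooled per stream) and writing the
#' calibrated probabilities back. PSM and site score streams are calibrated
#' independently.
#'
#' @param psms A PSM table with \code{psm_score} (and decoy flags).
#' @param what \code{"psm"} to fill \code{psm_probability} from
#'   \code{psm_score}; \code{"ptm"} to recalibrate \code{ptm_probabilities}
#'   treating the stored values as raw site scores.
#' @param bins Number of histogram bins.
#' @return The PSM table with probabilities filled in.
#' @export
calibratePsmTable <- function(psms, what = c("psm", "ptm"), bins = 100L) {
  what <- match.arg(what)
  if (what == "psm") {
    if (anyNA(psms$psm_score))
      stop("psm_score missing on some rows")
    cal <- histogramCalibrate(psms$psm_score, psms$is_decoy, bins = bins)
    psms$psm_probability <- calibrateScores(cal, psms$psm_score)
  } else {
    sc <- unlist(psms$ptm_probabilities, use.names = FALSE)
    dec <- rep(psms$is_decoy, lengths(psms$ptm_probabilities))
    cal <- histogramCalibrate(sc, dec, bins = bins)
    grp <- factor(rep(seq_len(nrow(psms)), lengths(psms$ptm_probabilities)),
                  levels = seq_len(nrow(psms)))
    psms$ptm_probabilities <-
      IRanges::NumericList(unname(split(calibrateScores(cal, sc), grp)))
  }
  psms
}
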