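## Shared toy builders and independent brute-force oracles.

## Build a ranked table directly from probability / decoy-flag vectors.
## psm probability is fixed at 1 so combined == ptm probability.
make_ranked <- function(p, decoy = logical(length(p)), peptide = NULL,
                        pos = NULL, spectrum = NULL,
                        cfg = DecoyConfig(decoyResidue = "A")) {
  n <- length(p)
  if (is.null(peptide))
    peptide <- ifelse(decoy, "AK", "SK")
  if (is.null(pos)) pos <- rep(1L, n)
  s <- S4Vectors::DataFrame(
    spectrum_id = if (is.null(spectrum)) sprintf("S%03d", seq_len(n)) else
      spectrum,
    peptide = peptide, charge = 2L, site_position = pos,
    residue = substring(peptide, pos, pos),
    psm_probability = rep(1, n), ptm_probability = p,
    combined_probability = p, is_decoy_site = decoy,
    protein = rep("P1", n), protein_position = rep(NA_integer_, n),
    psm_index = seq_len(n))
  rankSites(s, "combined", cfg)
}

## Per-row recomputation from scratch -- deliberately naive.
brute_model_flr <- function(p) {
  vapply(seq_along(p), function(k) sum(1 - p[seq_len(k)]) / k, numeric(1))
}
brute_decoy_flr <- function(decoy, tc, xc) {
  vapply(seq_along(decoy), function(k)
    min(1, 2 * (tc / xc) * sum(decoy[seq_len(k)]) / k), numeric(1))
}
brute_key_flr <- function(false) {
  vapply(seq_along(false), function(k) sum(false[seq_len(k)]) / k, numeric(1))
}
brute_q <- function(raw) {
  n <- length(raw)
  vapply(seq_len(n), function(k) min(raw[k:n]), numeric(1))
}

## Dyadic probabilities (multiples of 1/128) keep double sums exact.
random_dyadic <- function(n) sample(0:128, n, replace = TRUE) / 128

## Multiset of overlapping k-mers of a sequence string.
kmer_multiset <- function(x, k = 2L) {
  n <- nchar(x)
  sort(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

## Random protein string from the uniform 20-letter alphabet.
random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

## Candidate-dense residue frequencies with equal target and decoy counts
## (freq A = freq S + T + Y) and long tryptic peptides; the stress
## configuration used by the parity recovery checks.
parity_frequencies <- function() {
  other <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   c("A", "S", "T", "Y", "K", "R"))
  c(setNames(rep(0.54 / length(other), length(other)), other),
    A = 0.24, S = 0.08, T = 0.08, Y = 0.08, K = 0.02, R = 0.02)
}

## Same shape with the decoy three-fold rarer than the targets (X/T = 1/3).
rarity_frequencies <- function() {
  other <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   c("A", "S", "T", "Y", "K", "R"))
  c(setNames(rep(0.48 / length(other), length(other)), other),
    A = 0.12, S = 0.12, T = 0.12, Y = 0.12, K = 0.02, R = 0.02)
}

## Rank row index of the last row whose running true FLR is <= target.
true_flr_threshold <- function(tf, target) {
  ok <- which(tf <= target)
  if (!length(ok)) stop("true FLR never reaches ", target)
  max(ok)
}
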