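cfgA <- DecoyConfig(decoyResidue = "A")

## One confident site per protein at the given protein position.
site_rows <- function(proteins, positions, prob = 0.95) {
  n <- length(positions)
  S4Vectors::DataFrame(
    spectrum_id = sprintf("s%04d", seq_len(n)),
    peptide = rep("SK", n), charge = 2L, site_position = 1L,
    residue = "S", psm_probability = 1,
    ptm_probability = rep(prob, length.out = n),
    combined_probability = rep(prob, length.out = n),
    is_decoy_site = FALSE, protein = names(proteins)[seq_len(n)],
    protein_position = as.integer(positions), psm_index = seq_len(n))
}

test_that("nearest candidate offsets are signed, windowed, and exclude the
           site itself", {
  prot <- Biostrings::AAStringSet(c(P1 = "MASPK"))
  s <- site_rows(c(P1 = ""), 3L)  # S at protein position 3
  expect_identical(nearestResidueOffsets(s, prot, candidates = "A"), -1L)
  ## the site's own residue is excluded: nearest other S
  prot2 <- Biostrings::AAStringSet(c(P1 = "MSSPK"))
  expect_identical(nearestResidueOffsets(site_rows(c(P1 = ""), 3L), prot2,
                                         candidates = "S"), -1L)
  ## equidistant candidates resolve to the N-terminal (negative) offset
  prot3 <- Biostrings::AAStringSet(c(P1 = "GASAG"))
  expect_identical(nearestResidueOffsets(site_rows(c(P1 = ""), 3L), prot3,
                                         candidates = c("A", "G")), -1L)
  expect_identical(nearestResidueOffsets(site_rows(c(P1 = ""), 3L), prot3,
                                         candidates = "G"), -2L)
  ## nothing within the window -> NA
  prot4 <- Biostrings::AAStringSet(c(P1 = "KKKKKKKKKKKKSKKKKKKKKKKKK"))
  expect_identical(nearestResidueOffsets(site_rows(c(P1 = ""), 13L), prot4,
                                         candidates = "W", window = 10L),
                   NA_integer_)
  ## out-of-range site position errors with the record named
  expect_error(nearestResidueOffsets(site_rows(c(P1 = ""), 99L), prot,
                                     candidates = "A"),
               "outside its context.*s0001")
})

test_that("offset histograms normalize to one and pair with the STY profile", {
  h <- offsetHistogram(c(-1L, -1L, 2L))
  expect_equal(h$frequency[h$offset == -1], 2 / 3)
  expect_equal(h$frequency[h$offset == 2], 1 / 3)
  expect_equal(sum(h$frequency), 1)
  expect_equal(offsetHistogram(c(NA, 3L))$frequency, 1)
  expect_error(offsetHistogram(NA_integer_), "no offsets")
})

test_that("on i.i.d. uniform proteins, single-letter offset histograms are
           exchangeable", {
  set.seed(61)
  prots <- setNames(vapply(1:100, function(i) random_protein(500), ""),
                    sprintf("P%03d", 1:100))
  aa <- Biostrings::AAStringSet(prots)
  ## plant sites on every S at least 12 residues from the ends
  rows <- do.call(rbind, lapply(names(prots), function(acc) {
    pos <- which(strsplit(prots[[acc]], "")[[1]] == "S")
    pos <- pos[pos > 12 & pos < 488]
    if (!length(pos)) return(NULL)
    r <- site_rows(setNames(rep("", length(pos)), rep(acc, length(pos))), pos)
    r$protein <- acc
    r$spectrum_id <- sprintf("%s_%d", acc, pos)
    r
  }))
  hA <- offsetHistogram(nearestResidueOffsets(rows, aa, candidates = "A"))
  hG <- offsetHistogram(nearestResidueOffsets(rows, aa, candidates = "G"))
  common <- merge(hA, hG, by = "offset", all = TRUE)
  common[is.na(common)] <- 0
  expect_gt(nrow(rows), 1500)
  expect_lt(max(abs(common$frequency.x - common$frequency.y)), 0.05)
})

test_that("proximal profiles average combined probability by neighbor letter", {
  s <- S4Vectors::DataFrame(
    spectrum_id = sprintf("s%d", 1:4),
    peptide = c("GSK", "GTK", "ASK", "SAK"), charge = 2L,
    site_position = c(2L, 2L, 2L, 1L),
    residue = c("S", "T", "S", "S"), psm_probability = 1,
    ptm_probability = c(0.90, 0.84, 0.95, 0.80),
    combined_probability = c(0.90, 0.84, 0.95, 0.80),
    is_decoy_site = FALSE, protein = "P",
    protein_position = NA_integer_, psm_index = 1:4)
  prof <- proximalProbabilityProfile(s, offset = -1L, minProbability = 0)
  ## two sites with G at -1 average to 0.87; terminal site (pos 1) skipped
  expect_equal(prof$mean_probability[prof$residue == "G"], 0.87)
  expect_identical(prof$n_sites[prof$residue == "G"], 2L)
  expect_equal(prof$mean_probability[prof$residue == "A"], 0.95)
  expect_false("S" %in% prof$residue[prof$n_sites == 0])

  ## the 0.68 default filter excludes low-probability sites
  s$combined_probability <- c(0.90, 0.50, 0.95, 0.80)
  prof2 <- proximalProbabilityProfile(s, offset = -1L)
  expect_identical(sum(prof2$n_sites), 2L)  # 0.50 and the terminal row gone
  ## +1 neighbors
  prof3 <- proximalProbabilityProfile(s, offset = 1L, minProbability = 0)
  expect_true(all(prof3$residue %in% c("K", "A")))
})
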