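cfgA <- DecoyConfig(decoyResidue = "A")

test_that("residue counting is per PSM with multiplicity", {
  one <- psmTable(spectrum_id = "s1", peptide = "ASTYAK",
                  mod_positions = list(3L), ptm_probabilities = list(0.9),
                  psm_probability = 1)
  ctr <- countResidues(one, cfgA)
  expect_equal(targetCount(ctr), 3)
  expect_equal(decoyCount(ctr), 2)

  two <- rbind(one, one)
  two$spectrum_id <- c("s1", "s2")
  ctr2 <- countResidues(two, cfgA)
  expect_equal(targetCount(ctr2), 6)
  expect_equal(decoyCount(ctr2), 4)
  ## the unique-peptide variant collapses the duplicate
  ctr3 <- countResidues(two, cfgA, uniquePeptides = TRUE)
  expect_equal(targetCount(ctr3), 3)

  noDecoy <- psmTable(spectrum_id = "s1", peptide = "STYK",
                      mod_positions = list(1L),
                      ptm_probabilities = list(0.9), psm_probability = 1)
  expect_error(countResidues(noDecoy, cfgA), "absent from data")
  ## PSMs without a scored site do not contribute residues
  mixed <- rbind(one, psmTable(spectrum_id = "x", peptide = "AAAK",
                               mod_positions = list(integer()),
                               ptm_probabilities = list(numeric()),
                               psm_probability = 1))
  expect_equal(decoyCount(countResidues(mixed, cfgA)), 2)
})

test_that("model FLR is the running mean of local error probabilities", {
  expect_equal(modelFlr(make_ranked(c(1, 0.9, 0.8))), c(0, 0.05, 0.10))
  expect_equal(modelFlr(make_ranked(rep(1, 4))), rep(0, 4))
  expect_equal(modelFlr(make_ranked(rep(0.75, 5))), rep(0.25, 5))
})

test_that("decoy FLR reproduces the worked plug-in cases exactly", {
  ## T_c = X_c, 5 decoy sites among 100 rows -> 2 * 1 * 5/100 = 0.10
  decoy <- c(rep(FALSE, 95), rep(TRUE, 5))
  rt <- make_ranked(seq(0.999, 0.9, length.out = 100), decoy = decoy)
  flr <- decoyFlr(rt, FlrCounters(50, 50))
  expect_identical(flr[100], 0.10)
  ## T_c / X_c = 3, 2 decoy sites among 60 rows -> 2 * 3 * 2/60 = 0.20
  decoy <- c(rep(FALSE, 58), TRUE, TRUE)
  rt <- make_ranked(seq(0.999, 0.9, length.out = 60), decoy = decoy)
  expect_identical(decoyFlr(rt, FlrCounters(60, 20))[60], 0.20)
  ## no decoy sites -> zero everywhere; cap at 1 binds for extreme ratios
  rt0 <- make_ranked(c(0.9, 0.8))
  expect_equal(decoyFlr(rt0, FlrCounters(10, 2)), c(0, 0))
  rtc <- make_ranked(c(0.9, 0.8), decoy = c(TRUE, FALSE))
  expect_equal(decoyFlr(rtc, FlrCounters(100, 1)), c(1, 1))
  ## sensitivity variant: denominator counts only target rows
  rtd <- make_ranked(c(0.9, 0.8, 0.7), decoy = c(FALSE, TRUE, FALSE))
  expect_equal(decoyFlr(rtd, FlrCounters(10, 10), excludeDecoyRows = TRUE),
               c(0, 1, 1))  # 0/1, 2*1/1 capped, 2*1/2
})

test_that("answer-key FLR counts sites not matching the key", {
  key <- AnswerKey(peptide = c("SSK", "STK"), truePositions = list(1L, 2L))
  ## ten rows: first site wrong (pos 2 on SSK vs true 1), rest right
  p <- seq(0.99, 0.9, length.out = 10)
  rt <- make_ranked(p, peptide = rep(c("SSK", "STK"), c(4, 6)),
                    pos = c(2L, rep(1L, 3), rep(2L, 6)))
  expect_equal(answerKeyFlr(rt, key), 1 / 1:10)
  ## all matching -> zero
  rt2 <- make_ranked(p[1:4], peptide = rep("SSK", 4), pos = rep(1L, 4))
  expect_equal(answerKeyFlr(rt2, key), rep(0, 4))
  ## unknown peptide errors with its name
  rt3 <- make_ranked(0.9, peptide = "YYK", pos = 1L)
  expect_error(answerKeyFlr(rt3, key), "YYK")
})

test_that("answer-key filtering removes partials, count mismatches and other mods", {
  key <- AnswerKey(peptide = c("ASSTK", "TPEPK"),
                   truePositions = list(3L, 1L),
                   expectedModCount = c(1L, 1L))
  psms <- psmTable(
    spectrum_id = c("keep", "countmis", "partial", "unknown"),
    peptide = c("ASSTK", "ASSTK", "SSTK", "WWWK"),
    mod_positions = list(3L, c(2L, 3L), 2L, 1L),
    ptm_probabilities = list(0.9, c(0.5, 0.5), 0.9, 0.9),
    psm_probability = 1)
  out <- answerKeyFilter(psms, key)
  expect_identical(out$spectrum_id, "keep")
  removals <- S4Vectors::metadata(out)$removals
  expect_identical(removals$reason[removals$peptide == "ASSTK"],
                   "count mismatch")
  expect_identical(removals$reason[removals$peptide == "SSTK"],
                   "partial peptide")
  expect_identical(removals$reason[removals$peptide == "WWWK"], "not in key")

  psms$has_other_mods <- c(TRUE, FALSE, FALSE, FALSE)
  out2 <- answerKeyFilter(psms, key)
  expect_identical(nrow(out2), 0L)
  expect_true("additional modifications" %in%
                S4Vectors::metadata(out2)$removals$reason)
})

test_that("q-values are the running minimum from the bottom", {
  expect_equal(toQValues(c(0, 0.2, 0.1)), c(0, 0.1, 0.1))
  mono <- c(0.01, 0.02, 0.05)
  expect_equal(toQValues(mono), mono)
  expect_equal(toQValues(rep(0.3, 4)), rep(0.3, 4))
  expect_error(toQValues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("thresholding returns rows down to the last q <= alpha", {
  rt <- make_ranked(c(0.999, 0.98, 0.94), decoy = c(FALSE, FALSE, TRUE))
  est <- flrEstimate(rt, "model")
  s <- siteData(est)
  s$q_model <- c(0.001, 0.02, 0.06)
  est <- new("RankedSiteTable", sites = s, orderKey = "combined",
             decoyConfig = decoyConfig(rt))
  expect_identical(thresholdAt(est, 0.05, "model")$n_rows, 2L)
  expect_identical(thresholdAt(est, 1.0, "model")$n_rows, 3L)
  expect_identical(thresholdAt(est, 0.0005, "model")$n_rows, 0L)
  expect_error(thresholdAt(est, 0, "model"), "alpha")
  ## target-site count excludes decoy-residue rows
  expect_identical(thresholdAt(est, 1.0, "model")$n_target_sites, 2L)
  ## larger alpha never returns fewer rows
  alphas <- c(0.001, 0.01, 0.05, 0.1, 1)
  n <- vapply(alphas, function(a) thresholdAt(est, a, "model")$n_rows,
              integer(1))
  expect_true(all(diff(n) >= 0))
})

test_that("estimators match brute-force recomputation on random tables", {
  set.seed(42)
  key <- AnswerKey(peptide = "SAK", truePositions = list(1L))
  for (rep in 1:40) {
    n <- sample(1:50, 1)
    p <- sort(random_dyadic(n), decreasing = TRUE)
    decoy <- runif(n) < 0.3
    pos <- ifelse(decoy, 2L, 1L)
    rt <- make_ranked(p, decoy = decoy, peptide = rep("SAK", n), pos = pos)
    tc <- sample(10:500, 1); xc <- sample(1:500, 1)
    expect_identical(modelFlr(rt), brute_model_flr(siteData(rt)$ptm_probability))
    expect_identical(decoyFlr(rt, FlrCounters(tc, xc)),
                     brute_decoy_flr(siteData(rt)$is_decoy_site, tc, xc))
    falseRows <- siteData(rt)$site_position != 1L
    expect_identical(answerKeyFlr(rt, key), brute_key_flr(falseRows))
    raw <- decoyFlr(rt, FlrCounters(tc, xc))
    expect_identical(toQValues(raw), brute_q(raw))
  }
})
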