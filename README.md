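# phosphoFLR

Decoy amino acid estimation of the global false localization rate (FLR)
in phosphoproteomics.

Search engines report which S/T/Y residue of a peptide carries a
phosphate together with a localization probability — but that probability
comes from the engine's own model, and its calibration on real data is
largely unknown. `phosphoFLR` is for proteomics analysts and pipeline
developers who need an *independent* estimate of how many reported
phosphosites are on the wrong residue. The idea mirrors target-decoy
database searching: configure the search to also score the modification
on a **decoy amino acid** — a residue that cannot be phosphorylated, such
as alanine or leucine — so that every "phospho-Ala" hit is a known false
localization, and count those hits down the ranked site list.

At row *n* of a site list ranked by combined probability
(P<sup>PSM</sup> × P<sup>PTM</sup>), the package computes:

* **decoy FLR** = 2 (T<sub>c</sub>/X<sub>c</sub>) Σ<sub>1..n</sub> pX<sub>c</sub> / *n*,
  where T<sub>c</sub> and X<sub>c</sub> are the total target (S/T/Y) and
  decoy residue counts over the retained PSMs' peptides and
  Σ pX<sub>c</sub> is the running count of decoy-residue sites — capped
  at 1, independent of the engine's probability model;
* **model FLR** = Σ<sub>1..n</sub> (1 − P<sup>PSM</sup><sub>i</sub> P<sup>PTM</sup><sub>i</sub>) / *n*,
  the engine's own expectation;
* **answer-key FLR** = F<sub>c</sub>/*n*, exact mismatch counting for
  synthetic peptide libraries with known sites.

Raw estimates are monotonized into q-values (running minimum from the
bottom of the list) for thresholding at, say, 1, 5 or 10% FLR. Around
this core the package provides PSM-level target-decoy FDR filtering,
site expansion, multi-PSM site collapsing (binned maximum probability,
then spectral counts), histogram-based score calibration, de Bruijn
(k = 2) decoy protein database generation, decoy-suitability profiling
diagnostics, and a ground-truth simulator used to validate the
estimators.

## Worked example

Simulate search output with known ground truth, estimate FLR three ways,
and threshold at 5% decoy FLR:

```r
library(phosphoFLR)

cfg <- DecoyConfig(decoyResidue = "A")
sim <- simulateSites(nPsms = 5000, nProteins = 200, seed = 42)

psms    <- filterPsmFdr(computePsmFdr(sim$psms), alpha = 1)
ranked  <- rankSites(expandToSites(psms, cfg), "combined", cfg)
counters <- countResidues(psms, cfg)
counters
#> FlrCounters: T_c = 15353, X_c = 4998 (T_c/X_c = 3.072) over 5000 PSMs

est <- flrEstimate(ranked, c("model", "decoy", "key"),
                   counters = counters, key = sim$answerKey)
th <- thresholdAt(est, 0.05, method = "decoy")
th$n_target_sites
#> [1] 1504

tf <- trueFlr(est, sim$truth)
round(tf[th$n_rows], 4)
#> [1] 0.0244

collapseSites(est, by = "protein_site")
#> RankedSiteTable with 3157 site observations, ranked by combined probability
#> DecoyConfig: targets {S,T,Y}, decoy A
#>   decoy-residue sites: 219
```

The residue ratio T<sub>c</sub>/X<sub>c</sub> ≈ 3.07 reflects that S+T+Y
are about three times as frequent as alanine here, so each observed
phospho-Ala hit stands in for about three silent false localizations on
target residues (times the ×2 normalization). Accepting 1504 target
sites at the 5% decoy q-value threshold gives a realized true FLR of
2.4% — the decoy estimate is conservative when the decoy residue is
rarer than the targets, by design. File-based workflows (`readPsmTable`,
`runPipeline`) and a command-line front end
(`inst/scripts/flr.R`, subcommands `simulate`, `decoydb`, `calibrate`,
`psm-fdr`, `sites`, `estimate`, `collapse`, `profile`, `all`) wrap the
same functions; the interchange format is a documented TSV, one row per
PSM.

## Package layout

| Where | What |
| --- | --- |
| `R/psmFdr.R` | target-decoy PSM FDR and filtering |
| `R/sites.R` | site expansion and ranking |
| `R/estimators.R` | the three FLR estimators, q-values, thresholds |
| `R/calibration.R` | target/decoy histogram score calibration |
| `R/collapse.R` | multi-PSM site collapsing |
| `R/profiling.R` | decoy-suitability diagnostics |
| `R/decoyDatabase.R` | de Bruijn decoy FASTA generation |
| `R/simulate.R` | ground-truth simulator and true FLR |
| `vignettes/decoy-amino-acid-flr.Rmd` | methods, assumptions, design choices |
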