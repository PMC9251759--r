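---
title: "Estimating the false localization rate with decoy amino acids"
author: "phosphoFLR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the false localization rate with decoy amino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoFLR)
```

## The problem

Phosphoproteomics pipelines report, for every peptide-spectrum match
(PSM), which serine, threonine or tyrosine carries the phosphate, together
with a localization score or probability. Those scores come from the
software's own model, calibrated (if at all) on synthetic spectra, and
their reliability on real data is largely unknown. The *global false
localization rate* (FLR) — the fraction of reported sites placed on the
wrong residue among all sites accepted at a threshold — therefore needs an
estimator that does not trust the localization model it is auditing.

The decoy amino acid idea transfers the logic of target-decoy database
searching to localization: the search is configured to also score the
modification on a residue that cannot biologically carry it (alanine or
leucine are good choices; glycine, glutamate, aspartate and proline are
supported for method evaluation). Every "phospho-Ala" site is then a known
false localization, and counting such hits down a ranked site list yields
an FLR estimate that is independent of the scoring model.

## The three estimators

All estimators operate on a site table ranked by a non-increasing key:
either the **combined probability** — PSM probability times localization
probability, whose complement is the site's local error probability — or
the localization probability alone (useful when the search database is too
small for PSM probabilities to be meaningful). At row $n$ of the ranked
list:

**Model FLR** sums the local error probabilities:
$$\mathrm{FLR}_{\mathrm{model}}(n) = \frac{1}{n} \sum_{i=1}^{n}
\bigl(1 - P^{\mathrm{PSM}}_i P^{\mathrm{PTM}}_i\bigr).$$
It is exact when the reported probabilities are perfectly calibrated and
inherits every defect of their calibration; it serves as the
software-internal reference the decoy method is compared against.

**Decoy FLR** counts observed decoy-residue sites $\sum_1^n pX_c$ and
scales them by residue availability:
$$\mathrm{FLR}_{\mathrm{decoy}}(n) = \frac{2\,(T_c/X_c)
\sum_{i=1}^{n} pX_{c,i}}{n},$$
capped at 1, where $T_c$ and $X_c$ are the total counts of target (S/T/Y)
and decoy residues over the peptides of the retained PSM set
(`countResidues()`, counted with multiplicity per PSM). A random wrong
assignment lands on a decoy residue with odds $X_c : T_c$, so
$(T_c/X_c)\sum pX_c$ models the *silent* false localizations sitting on
target residues; the factor 2 adds the observed decoy hits themselves on
the assumption that wrong hits split between target and decoy residues in
proportion to their counts. When the decoy residue is rarer than the
targets this factor deliberately over-corrects, making the estimator
conservative — preferable to under-correction for a quality-control
statistic.

**Answer-key FLR**, for synthetic peptide libraries with known true sites,
is the exact count of key mismatches over $n$. Before using it, tables are
filtered for comparability (`answerKeyFilter()`): peptides absent from the
key, proper substrings of key peptides, rows whose phosphate count differs
from the expected count, and rows carrying other variable modifications
are removed, with reasons recorded.

Raw estimates are monotonized into q-values by a running minimum from the
bottom of the list (`toQValues()`), and `thresholdAt()` accepts all rows
down to the last q-value at or below the requested FLR, reporting the
count of target-residue sites (the sensitivity measure). A threshold the
capped decoy estimator can never reach is reported as not available rather
than as a count.

## Design choices where the design was open

* **Probabilities, not PEPs, in the interchange format.** Pipelines
  natively report probabilities of correctness; local error probabilities
  are derived as $1 - p$ at the point of use. Tables mixing rows with
  native probabilities and rows awaiting score calibration are rejected as
  invalid rather than silently mixed.
* **FDR formula.** PSM-level FDR uses cumulative decoys over cumulative
  targets ($D/T$); the $(D+1)/T$ variant is available via a flag. At tied
  scores decoys rank above targets, which can only make estimates more
  conservative; the same tie-break is used for decoy sites in the ranked
  site list.
* **Residue counting.** $T_c/X_c$ is computed over the full peptide
  sequence of every PSM contributing at least one scored site, with
  multiplicity (a peptide seen in $k$ PSMs counts $k$ times); a
  unique-peptide variant exists for sensitivity analysis. Decoy-residue
  rows stay in the denominator $n$ — they are part of the ranked list
  being thresholded.
* **Collapsing.** Multiple PSMs observing one site collapse to the
  maximum probability, floored to two decimals, with ties between bins
  broken by supporting-PSM count, then by the unbinned maximum, then by
  ranked order. Flooring is order-preserving at bin edges (0.9999 stays in
  bin 0.99); an epsilon of $10^{-9}$ guards against decimal-representation
  artifacts such as $0.29 \times 100 = 28.999\ldots$. Counters for the
  decoy estimator are kept from the uncollapsed PSM set: collapse discards
  rows, not evidence, and recomputing residue availability on the
  collapsed table would couple the normalization to the collapse
  granularity. No probability combination across PSMs is attempted — PSMs
  of one site are not independent tests, and the model estimator's
  calibration assumption does not survive collapse.
* **Score calibration.** Engines reporting only raw scores are calibrated
  by target/decoy histogram binning: 100 equal-width bins by default, bin
  PEP $\min(1, D_b/T_b)$, empty-target bins inheriting the nearest
  populated bin (ties toward the lower-score, more conservative side), and
  weighted pool-adjacent-violators pooling so the score-to-probability map
  is monotone. PSM and site score streams are calibrated independently.
* **Profiling diagnostics.** Candidate decoys are profiled by (i) the
  signed distance from confident sites (default: 5% model FLR) to the
  nearest candidate residue within ±10 residues, compared with the same
  distribution for S/T/Y — a good decoy should mimic the target
  distribution, since mislocalizations favor nearby residues; and (ii) the
  mean combined probability of confident sites (≥ 0.68 by default, the
  typical minimum combined probability at a 5% decoy-FLR cutoff) grouped
  by the amino acid at offset −1 or +1. Equidistant ties resolve to the
  N-terminal offset; protein context is used when coordinates are
  available, otherwise the peptide with a warning.
* **Decoy databases.** Decoy proteins are random Eulerian paths over the
  dipeptide (de Bruijn, $k = 2$) graph of each target, preserving length,
  composition and the exact dipeptide multiset. Path endpoints necessarily
  equal the original first and last residues, and no attempt is made to
  preserve tryptic termini. Seeds are derived per entry from the run seed
  and recorded in the decoy headers, so databases are byte-reproducible.

## What the simulator emulates

`simulateSites()` generates the statistical structure the estimators
assume, at the probability level. Random proteins (gamma-distributed
lengths, mean 350, configurable residue frequencies) are digested
tryptically (cut after K/R, not before P, up to 2 missed cleavages,
length 7–30); each usable peptide — at least one target residue and at
least two candidate (target or decoy) residues — carries one fixed true
phosphosite, so the answer key is unambiguous. Each PSM draws a
localization probability from Beta(8, 1) (right-skewed, emulating
confident localizations; arbitrary but configurable) and a PSM probability
from Beta(99, 1) (mean 0.99, emulating a PSM list already filtered to 1%
FDR). The row is correct when independent Bernoulli draws at both
probabilities succeed, so **the probability a row is correct equals its
combined probability** — calibrated by construction. Incorrect rows are
relocated onto another candidate residue of the peptide, uniformly or
with weight proportional to 1/distance, optionally with a multiplicative
bias onto a decoy residue immediately N-terminal of the true site
(emulating motif-driven confusion such as Gly–Ser, which makes a decoy
over-conservative).

A structural point the validation accounts for: a wrong row can never
land on the true site itself, so among wrong rows the decoy residue
receives a share $X/(T + X - 1)$ of candidate positions per peptide
rather than $X/(T + X)$. The decoy estimator therefore carries an
inherent inflation of roughly $c/(c-1)$, where $c$ is the candidate
count per peptide. The parity and rarity recovery checks use
candidate-dense frequency tables (decoy at 24% with targets summing to
24%, or all four residues at 12%, cleavage residues at 2% each, hence
long peptides with $c \approx 8$) so that this inflation stays well
inside Monte-Carlo tolerance; these frequencies are a stress
configuration for estimator validation, not a model of a real proteome,
where candidate density is lower and the inflation correspondingly
larger relative to a 5% FLR.

The simulator does **not** emulate: spectra or fragmentation; multiple
phosphosites per PSM; shared peptides between proteins; sequence-database
decoy PSMs (PSM-level FDR is exercised with constructed tables);
correlated errors between PSM identification and localization; or
engine-specific score distributions. Passing recovery tests therefore
shows the estimators are correct under their own generative assumptions —
it does not certify calibration of any particular search engine's
probabilities on real data, which is precisely why the decoy estimator
exists.

## Validation conditions and problem sizes

The test suite validates, among other properties: exact equivalence of
all three estimators with brute-force per-row recomputation on 200 random
tables of up to 50 rows (probabilities on a dyadic grid so sums are
exact); hand-derived plug-in values of the decoy formula; model-FLR
recovery of the true FLR at 1/5/10% thresholds on 20,000 calibrated rows
within 3 Monte-Carlo standard errors; decoy-FLR recovery at residue
parity (10,000 rows) and conservatism with a three-fold rarer decoy
(5 × 4,000 rows, Monte-Carlo mean compared against
$\mathrm{true} \times 2T_c/(T_c+X_c)$); q-value and threshold
monotonicity; collapse determinism under input permutation; dipeptide
preservation over 500 random proteins up to length 2,000; offset
histogram letter-exchangeability on uniform proteins; and the directional
over-conservatism induced by motif bias. Monte-Carlo standard errors are
computed from the realized data (binomial/Poisson counts), not assumed.
These sizes keep the whole suite under about a minute while leaving the
stochastic checks adequately powered.

## Known limitations

* The decoy estimator yields global FLR only; it has too few decoy
  observations at stringent thresholds to support per-site (local) error
  estimates.
* Conservatism depends on the decoy's sequence context: a decoy residue
  enriched immediately next to true sites (as glycine is before
  phosphoserine) attracts excess mislocalization and overestimates FLR;
  the profiling module exists to detect exactly this.
* With a decoy much rarer than the targets, the ×2 normalization makes
  estimates strongly conservative and the cap at 1 can make 10%-FLR
  thresholds unattainable.
* The q-value presentation assumes the ranked list is exchangeable at
  equal scores; heavy score discretization (many exact ties) makes
  boundary behavior depend on the documented tie-breaks.
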