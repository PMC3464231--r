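---
title: "Methods: ING4/NF-κB signature scoring and survival stratification"
author: "ing4nfkb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ING4/NF-κB signature scoring and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ing4nfkb)
```

# The scientific problem

ING4 (Inhibitor of Growth 4) is a candidate tumor suppressor whose loss in
breast tumors is associated with activation of NF-κB — detectable as
nuclear phosphorylated p65/RelA (p-p65) on tissue microarrays — and with
elevated expression of NF-κB-target genes. The analytical chain this
package implements connects four kinds of evidence:

1. **RT-qPCR fold changes** identify NF-κB-target genes induced by PMA in a
   control breast-cancer line and repressed when ING4 is overexpressed;
   the nested ≥2× and ≥4× repression tiers define gene signatures.
2. **TMA immunohistochemistry** scores ING4 and p-p65 on ordinal 0–3
   scales per 0.6 mm punch; tumor-level calls are tested for association
   with each other and with pathology (lymph-node status) by Fisher's
   exact test.
3. A **median-vote gene score** summarizes signature expression per tumor
   in public expression cohorts.
4. **Survival analysis** asks whether ING4-low status, or a high signature
   score, stratifies disease-free survival.

# Models and procedures

## ΔΔCt quantification

Replicate Ct values are averaged per (gene, condition) *before* any
differencing (standard ΔΔCt practice; averaging folds instead would be
biased by Jensen's inequality and is not offered). Then

$$\Delta\Delta C_t = (Ct_{g,c} - Ct_{ref,c}) - (Ct_{g,b} - Ct_{ref,b}),
\qquad \text{fold} = 2^{-\Delta\Delta C_t},$$

with amplification efficiency fixed at 2 (no efficiency correction — a
deliberate non-goal). Two exact invariances follow and are
property-tested: swapping condition and baseline inverts the fold, and
adding a constant to every Ct (a plate offset) leaves it unchanged.

## The signature-derivation cascade

* **Induced**: control-line PMA fold strictly greater than 2
  ("more than 2-fold" is read as a strict inequality).
* **Repressed tiers**: repression ratio = control-line induction fold
  divided by the ING4-line induction fold, restricted to induced genes;
  tier membership uses ratio ≥ 2 and ratio ≥ 4. The ≥ convention is taken
  from the "4-fold or higher" tier wording and applied to the 2-fold tier
  for consistency; whether the original 2-fold rule was strict at exactly
  2.0 is not documented anywhere we know of, and boundary cases are
  vanishingly rare for continuous fold estimates. The tiers always nest:
  repressed4 ⊆ repressed2 ⊆ induced.
* The ratio-of-induction-folds definition matches the published example
  arithmetic (IL8: 1070-fold vs 35-fold ⇒ ratio ≈ 30.6). A direct
  ING4-vs-control contrast under PMA can be substituted by passing
  `ratios=` to `deriveSignature()`.

Full gene lists are inputs (`readGeneSet()`), never hard-coded: the
package derives signatures from whatever fold table it is given.

## TMA scoring and association

A tumor's IHC score is the arithmetic mean of its evaluable punches
(2–3 per tumor; missing punches dropped; tumors with no evaluable punch
are flagged and excluded per-marker, not listwise, so each analysis keeps
its own maximal n). Calls use the 1.5 cutoff with the boundary on the high
side (`score < 1.5` → low, `score ≥ 1.5` → high). Display percentages
round to the nearest integer with halves away from zero — the convention
that reproduces printed report values such as 34% for 77/227.

`fisherExact2x2()` uses the two-sided point-probability definition: with
margins fixed, p sums the hypergeometric probabilities of all tables whose
point probability is at most the observed one, compared with a relative
tolerance of 1e-9 so float ordering cannot flip a tie. The suite checks it
exhaustively against a binomial-coefficient enumeration oracle on every
table with total ≤ 30, and against `stats::fisher.test` on random tables.

## The median-vote gene score

For each signature gene the median expression is computed *within the
dataset being scored* (midpoint interpolation at even n; medians are never
transferred between datasets, because platforms and normalizations
differ). A gene votes +1 for a sample strictly above its median; ties and
below-median values vote 0. Consequences worth knowing:

* Scores are invariant under any strictly increasing per-gene transform
  (log, scaling, ranks) — property-tested — so the score is robust to
  monotone normalization differences.
* With distinct values exactly ⌊n/2⌋ samples vote 1 per gene; ties only
  lower that count. An all-constant gene contributes nothing.
* Genes absent from a dataset are dropped with a warning and the
  attainable score range shrinks; the fitted `ScoreModel` records them.

Group comparison is the unpaired two-tailed pooled-variance t-test
(df = n₁+n₂−2). The degenerate zero-variance/zero-difference case reports
p = 1 with a warning rather than NaN.

The ING4-low/high split used alongside the score is, by default, the
marker's within-dataset median with ties going low — chosen for symmetry
with the score's own ≤-median ⇒ 0 convention, and because no published
rule exists for this split. Every splitting function honors an explicit
cutoff with the same at-or-below rule, which makes `median` policy and
`explicit(median value)` exactly equivalent even with ties at the median.
(The *IHC* dichotomization deliberately differs: its `< 1.5` → low rule is
the published one.)

## Survival machinery

All estimators are implemented from first principles, with the survival
package used only as an independent cross-check in the test suite.

* **KM**: product-limit estimator over distinct observed times; at a tied
  time, events precede censorings (censored individuals remain at risk at
  that time). Without censoring the curve equals the empirical survival
  function exactly.
* **Log-rank**: at each distinct event time, the group-1 event count is
  compared to its hypergeometric expectation; χ² = (O₁−E₁)²/V on 1 df.
  Zero total variance (no informative event times) is an error, not a
  silent p = 1.
* **Hazard ratio**: the default is the Mantel–Haenszel estimator
  ln HR = (O₁−E₁)/V, SE = 1/√V — the natural companion of the log-rank
  test. Because V is computed under the null, this estimator is known to
  overshoot |ln HR| for large effects; for *parameter-recovery* claims the
  package therefore offers `method = "cox"`, a one-covariate Cox partial
  likelihood maximized by Newton–Raphson (Breslow ties, tolerance 1e-9 on
  the step, ≤30 iterations), which is asymptotically unbiased and is what
  the calibration checks use. The ratio is reported for the first factor
  level relative to the second; swapping labels inverts it exactly.
* **ROC cutoff**: candidate cutoffs are the midpoints between adjacent
  distinct marker values; "positive" means marker below the cutoff (low
  marker predicts the event, the direction relevant for a tumor
  suppressor). The cutoff maximizing Youden's J is returned, with ties
  broken toward higher sensitivity and then the lower cutoff — a fully
  deterministic rule, since the optimality criterion behind published
  "ROC-optimal" cutoffs is rarely stated.

# The synthetic-data generators

`simConfig()` fixes the study conditions; each generator derives an
independent RNG sub-stream from the global seed (fixed offsets), so adding
a generator never perturbs existing streams and identical config + seed
reproduce outputs byte-for-byte.

* **TMA cohort** (default 249 tumors, matching the array scale the
  package targets; 2–3 punches with P(triple) = 0.5; punch noise
  SD 0.3 score units): a latent per-tumor ING4 level uniform on [0, 3];
  punches are the rounded noisy latent clamped to 0–3. p-p65-high status
  is Bernoulli with log-odds `qlogis(0.25) + 1.5·(1.5 − latent ING4)`
  (≈25% high at the cutoff, negative coupling); lymph-node-positivity odds
  (baseline 0.30) are multiplied by 3 for ING4-low/p-p65-high tumors.
* **Expression cohort** (default 60 samples — the scale of the public
  cohorts of interest — with 25 signature genes and 50 independent filler
  genes): ING4 ~ LogNormal(6, 0.5); each signature gene is its own
  Normal(8, 1) baseline minus β·z(log ING4) plus Normal(0, 1) noise
  (default β = 1, a visible but not overwhelming coupling); survival is
  exponential with hazard 0.1·HR^{I(ING4 ≤ median)} per time unit
  (default true HR = 3) — the same median split the scoring default uses,
  so generator truth and pipeline estimate refer to the same contrast.
  Censoring is independent exponential with rate calibrated so the
  baseline arm's expected censored fraction equals `censorRate`
  (default 0.2); an exponential censor keeps censoring non-informative
  while leaving the proportional-hazards structure exactly true.
* **Ct tables**: GAPDH constant at Ct 20; targets at baseline Ct 25
  shifted by −log₂(fold) under PMA, with Normal replicate noise
  (default SD 0.2 cycles, 3 replicates).

What the generators do **not** emulate: probe effects, batch structure,
array-normalization artifacts, non-proportional hazards, informative
censoring, or pathologist-specific scoring behavior. Green tests therefore
demonstrate that the estimators recover truth under the stated statistical
model — not that any particular real dataset satisfies that model.

# Calibration checks and problem sizes

The test suite and `scripts/acceptance.R` verify, at sizes chosen to keep
a full run in tens of seconds on one core:

* log-rank type-I error within [0.03, 0.07] at α = 0.05 over 1000 null
  simulations (50 per arm, exponential, ~20% censoring);
* Cox recovery of programmed HR ∈ {1, 2, 3} within 0.25 on the log scale
  at 500 patients per arm;
* ~95% CI coverage of the null HR over 500 replicates (accepted band
  0.92–0.98, the 3-SD binomial range at 500 replicates);
* qPCR fold recovery: exact at zero noise; within ±25% in ≥95% of 200
  replicates at SD 0.2 cycles and 3 replicates;
* direction recovery on anti-correlated cohorts (β = 2, n = 200): the
  ING4-low group's mean score exceeds the ING4-high group's by more than
  20% of the gene-set size, and the high-score group has worse KM
  survival;
* the Fisher test against exhaustive enumeration for all totals ≤ 30.

# Known limitations

* Published cohort-level numbers that depend on proprietary downloads
  (specific GEO/NKI accessions), on a supplementary gene list, or on an
  unstated ROC criterion are not reproduced here; the package instead
  validates its machinery on calibrated synthetic truth. The optional SOFT
  reader parses local GDS files only and never touches the network; its
  duplicate-probe policy (keep the probe with the highest mean expression;
  `collapse = "first"` as the alternative) is this package's documented
  choice, as no collapse rule is published for the original analyses.
* The Mantel–Haenszel HR is reported alongside the log-rank test for
  interpretability but should not be used for unbiased effect estimation
  at large effects — use `method = "cox"`.
* No multivariate Cox regression, competing risks, interval censoring,
  multi-reference-gene qPCR normalization, or weighted/continuous
  (ssGSEA-style) signature scores.
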