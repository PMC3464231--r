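# ing4nfkb

Low expression of the ING4 tumor suppressor marks an aggressive subset of
breast tumors in which the NF-κB pathway is constitutively active. This
package implements the complete computational chain used to study that
axis, for analysts working with tissue-microarray (TMA)
immunohistochemistry scores, RT-qPCR panels, and public breast-tumor
expression cohorts with follow-up:

* **ΔΔCt qPCR analysis and signature derivation** — fold change
  `2^(−ΔΔCt)` with a reference gene (GAPDH), and the filter cascade that
  selects NF-κB-target genes induced more than 2-fold by PMA and then
  repressed by ING4 at ≥2× or ≥4× (the two signature tiers), plus the
  luciferase-reporter normalization (RLU/µg protein/`luc2` copies against a
  qPCR standard curve).
* **TMA IHC statistics** — per-tumor averaging of 2–3 ordinal punch scores
  (0–3), the `<1.5` low vs `≥1.5` high dichotomization, 2×2 contingency
  tables with report-style rounded percentages, and a from-scratch
  two-sided Fisher exact test (point-probability definition).
* **Median-vote gene score** — each signature gene votes +1 for a tumor
  expressing it strictly above the gene's median *within that dataset*;
  the per-tumor score is the vote sum, compared between marker groups with
  a pooled two-tailed t-test.
* **Survival stratification** — ROC/Youden optimal-cutoff selection,
  Kaplan–Meier product-limit curves, the two-group log-rank test, and
  hazard ratios (Mantel–Haenszel `exp((O−E)/V)` or a one-covariate Cox
  partial-likelihood fit), all implemented from first principles.
* **Synthetic cohorts with known ground truth** — seeded generators for
  punch tables (latent ING4 coupled to p-p65 and lymph-node status),
  expression cohorts (signature genes negatively coupled to ING4,
  exponential survival with a programmed hazard ratio), and Ct tables
  realizing specified fold changes, so every stage is testable end to end.

The central container is `ExpressionCohort`, a `SummarizedExperiment`
subclass carrying the genes × samples matrix plus per-sample `time`/`event`
annotation; results are S4 classes (`ScoreModel`, `ScoreResult`,
`SignatureDerivation`, `KMCurve`, `LogrankResult`, `HazardRatioResult`,
`CutoffResult`) with accessors.

## Worked example

Simulate a 120-tumor cohort in which 25 signature genes are repressed by
ING4 (coupling β = 2) and ING4-low tumors recur at 3× the baseline hazard,
then score and stratify it:

```r
library(ing4nfkb)
cfg    <- simConfig(seed = 42, nSamples = 120, beta = 2, trueHR = 3)
sim    <- genExpressionCohort(cfg)
cohort <- sim$cohort

model  <- fitScoreModel(cohort, sim$signatureGenes)
res    <- scoreSamples(cohort, model)
res
#> ScoreResult: 120 sample(s), 25 gene(s); score range 0 - 25

cmp <- compareGroupScores(scores(res), splitByMarkerGene(cohort, "ING4"))
#> mean score ING4-low 21.2 vs ING4-high 3.8 (t = 21.10, p = 7.3e-42)

strat <- stratifyAndCompare(cohort, "ING4", cutoffPolicy = "roc")
strat$logrank
#> Log-rank test: chisq = 18.91 on 1 df, p = 1.371e-05
#>   O: low 42, high 68  E: low 23.88, high 86.12
strat$hazardRatio
#> HR = 2.84 (95% CI 1.77-4.55; mantelhaenszel)
```

ING4-low tumors carry the high signature scores (21.2 vs 3.8 of a possible
25 — the programmed negative coupling recovered by the median-vote score)
and nearly three times the recurrence hazard; the HR estimate brackets the
programmed truth of 3.

Desk-scale checks against published count tables work directly on the
contingency machinery:

```r
tab <- matrix(c(48, 118, 29, 33), 2, byrow = TRUE,
              dimnames = list(pp65 = c("low", "high"),
                              ING4 = c("low", "high")))
rowPercents(tab)        # 29% / 47% ING4-low in p-p65-low / -high rows
fisherExact2x2(tab)     # 0.0177
```

An end-to-end run (`runPipeline(runConfig(outDir = "out", seed = 1))`) or
the shell wrapper `inst/scripts/ing4-pipeline.R` executes
simulate → qPCR folds → signature derivation → TMA association → scoring →
survival, writing TSV/JSON results plus a `manifest.json` of config and
output hashes; reruns with the same seed are byte-identical.

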