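# hladose

Rejection-risk modelling for kidney-transplant cohorts stratified by
low-resolution HLA match, for biostatisticians and transplant researchers
working where only standard (A/B/DRB1 antigen-level) typing is available.
Given a per-patient table of match count (0–6 of 6 antigens), daily
tacrolimus dose (mg) and a binary rejection outcome, the package answers
two questions:

1. **Was dosing uniform across match strata?** A validation stage —
   completeness gate, per-stratum Shapiro–Wilk, Levene's test, one-way
   ANOVA of dose on stratum — certifies (or flags) that dose allocation
   cannot confound risk comparisons between strata.
2. **How much rejection risk does dose escalation remove, per stratum?**
   A constrained, ridge-penalized logistic dose–response model is fitted
   separately at each of the seven match fractions
   (0, 0.17, 0.33, 0.5, 0.67, 0.83, 1), and absolute/relative/expected
   risk reductions are derived with bootstrap confidence intervals and
   ROC/AUC discrimination.

## The model

Within match stratum *g*, rejection is Bernoulli with

```
p(x) = 1 / (1 + exp(-(b0 + b1 x)))        x = daily dose (mg)
```

and the coefficients minimise the ridge-penalized negative log-likelihood

```
L(b) = -Σᵢ [ yᵢ ln p(xᵢ) + (1-yᵢ) ln(1-p(xᵢ)) ] + λ (b0² + b1²)
```

subject to probability floors `p(x_min) ≥ 0.001` and `p(x_max) ≥ 0.001`
at the cohort-wide dose extremes, which keep predictions clinically
plausible at very high doses. λ is chosen per stratum by seeded,
outcome-stratified 5-fold cross-validation over a log-spaced grid. The
objective is convex and each floor is a half-plane, so the optimum is
unique; the solver finds it exactly from the interior Newton solution,
the two constraint boundaries and their vertex.

From the fitted endpoints `p_min = p(x_min)` (low-dose risk) and
`p_max = p(x_max)`:

| metric | definition | meaning |
|---|---|---|
| ARR | `p_min − p_max` | absolute risk reduction from dose escalation |
| RRR | `ARR / p_min` | fraction of baseline risk eliminated (×100 = %) |
| ERR | `n · ARR` | expected rejection events prevented in the stratum |

`cohort_benefit()` totals ERR across strata to locate the match range
where high-dose therapy prevents the most events cohort-wide.

A seeded synthetic-cohort generator (`generate_cohort()`) reproduces the
structure the analysis assumes — 519 records across the 7 strata, doses
i.i.d. from one law shared by all strata so the ANOVA null holds by
construction, outcomes from stratum-specific logistic curves — so the
whole pipeline is exercisable without patient data. See the methods
vignette (`vignettes/rejection-risk-methods.Rmd`) for the modelling
choices and their rationale.

## Worked example

```r
library(hladose)
report <- run_pipeline(pipeline_config(seed = 2))
print(report)
```

```
Rejection-risk analysis report (seed 2)
Cohort: 519 records
ANOVA (dose ~ match stratum): F = 1.172, p = 0.3198
Total expected rejections prevented: 8.411; AUC = 0.9410
Flags:
  ! normality: Shapiro-Wilk rejects in 6 stratum(s) (advisory; ANOVA is robust here)
  ! homogeneity: Levene p = 0.03067 < alpha (variances may differ)
```

The ANOVA p = 0.32 says mean dose does not differ across match strata
(the generator draws all strata from one dose law, so this is the null
behaving as designed; the Levene flag at p = 0.031 is a type-I event at
α = 0.05 and is advisory only). `render_tables(report)` prints the
completeness, normality, homogeneity, ANOVA (Source/SS/df/MS/F/p) and
per-stratum risk tables; for seed 2 the risk table shows the two strata
that drew rejection events carrying all the estimated benefit, e.g.

```
 match_level   n   p_min p_max     arr    rrr rrr_percent   err
        0.17  95 0.03833 0.001 0.03733 0.9739       97.39 3.547
        0.67  95 0.05220 0.001 0.05120 0.9808       98.08 4.864
```

while event-free strata sit flat at the probability floor (ARR = 0) and
are flagged quasi-separated — with ~2 expected events per 519 records
under the anchored risk curves, that sparsity is the realistic regime,
not an artifact. `write_report_bundle(report, dir)` writes the cohort
CSV, a full-precision JSON report and per-table TSVs, byte-identical
across re-runs with the same seed.

A thin CLI over the same functions ships in `inst/cli/hladose.R`
(`generate`, `validate`, `fit`, `report`, `run` subcommands).

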