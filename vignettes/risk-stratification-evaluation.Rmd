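---
title: "Evaluating primary-care risk stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating primary-care risk stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskstrat)
```

## The problem

Primary-care practices stratify their patient panels into four ordered risk
tiers — low, moderate, high, very high — and concentrate care-management
resources on the top tier. Two questions follow. First, how much does a
practice's own tiering (clinical intuition, an algorithm, or an algorithm
whose output clinicians adjudicate) agree with a standardized
hierarchical-condition-category (HCC) score tiered the same way? Second,
which flag better predicts next year's adverse utilization: two or more
emergency-department (ED) visits, one or more hospitalization, or
expenditures of $30,000 or more?

`riskstrat` implements that evaluation end to end: an HCC-style scoring
engine, size-matched tier cut-points, agreement statistics, paired
diagnostic-performance comparisons, and a calibrated synthetic population
so the whole pipeline is testable without protected health data.

## The HCC-style score

A model is three tables: a diagnosis-code-to-condition-category map,
dominance rules (a more severe category suppresses milder related ones),
and nonnegative weights for categories and age-sex cells. For a patient
with age $a$, sex $s$ and code set $C$,

$$\mathrm{score} = w_{\mathrm{demo}}(s, \mathrm{band}(a)) +
  \sum_{c \in H(M(C))} w_c,$$

where $M$ maps codes to categories (unmapped codes are skipped and
counted — real EHR feeds are dirty) and $H$ applies dominance rules to a
fixpoint. Rules are applied in simultaneous rounds: every rule whose
dominant category is present at the start of a round removes its
suppressed category, and rounds repeat until nothing changes, so chains of
rules resolve deterministically. Flat rule sets (the common case) converge
in one round; the fixpoint is a conservative generalization. Age bands are
half-open $[lo, hi)$ so membership is unambiguous at boundaries. Scores
are not clamped to any observed range.

The packaged `toy_hcc_model()` has 8 categories over a toy vocabulary and
three dominance rules. It is licensing-free and desk-testable; users can
supply real code maps and coefficient tables in the same three-CSV format
(`load_hcc_model()`). Reproducing any official coefficient set is a
non-goal.

## Tiers and outcome cut-points

`fit_cutpoints()` chooses thresholds $c_1 < c_2 < c_3$ at empirical
quantiles of the score so tier sizes match target proportions (default
40/30/20/10). Tied scores are never split across a boundary: the
threshold moves to the nearest distinct value, accepting unequal tier
sizes instead of random splitting — deterministic and auditable. The
assignment rule is half-open with an inclusive top: a score exactly at
$c_3$ is very high. `high_risk_flag()` flags only the single top tier by
default; whether "high risk" should instead mean the top two tiers is
genuinely open, so `run_study()` exposes `high_risk_rule =
"high_or_above"` as a switch.

Outcomes dichotomize at fixed cut-points (default $30,000, 2 ED visits, 1
hospitalization), all inclusive: "over $30,000" is implemented as
$\ge 30{,}000$, matching the threshold's symbolic form rather than the
looser phrase. The cut-points were designed to capture roughly the top
decile of patients, who carry about two thirds of total spend;
`select_expenditure_cutpoint()` reproduces that selection: the largest
threshold whose exceeders jointly account for at least the target share of
total expenditure. Cut-points are naturally calibrated on prior-year
outcomes, but prediction is evaluated on follow-year outcomes; both
windows are selectable (`window = "prior"`/`"follow"`, default follow,
since prediction of future risk is the point).

## Agreement

Two high-risk flags on the same patients cross-tabulate into a 2x2 table;
we report percent agreement, the both/either proportion (share of patients
flagged by either rater that both flagged), and Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from marginal products.
Qualitative labels use Landis-Koch bands closed on the right ((.2, .4] is
"fair", and so on). Kappa is computed on the binary high/not-high
collapse — the headline comparison — while `tier_crosstab()` also reports
the full 4x4 table, because "low risk in both" can be read either as the
lowest tier of the 4x4 table or as not-high in the collapse; reporting
both lets either reading be reproduced. A 4-level weighted kappa is out of
scope.

## Diagnostic performance and paired tests

Against each dichotomized outcome the flag yields the usual confusion
table and sensitivity, specificity, PPV, NPV and accuracy. A zero
denominator yields an explicit `NA` in results — never a silent zero. The
c-statistic is the tie-adjusted rank probability that an outcome-positive
patient outscores an outcome-negative one.

Because both flags are evaluated on the same patients, comparisons must be
paired:

* **Sensitivity.** Restricted to outcome-positive patients, the difference
  of sensitivities depends only on the discordant counts $b$ (flagged by A
  only) and $c$ (flagged by B only). We test $H_0\!: b = c$ with the exact
  binomial two-sided test ($2 \min$-tail at $p = 1/2$, capped at 1) when
  $b + c < 25$ and the normal approximation $z = (b-c)/\sqrt{b+c}$
  otherwise — McNemar's test on the positive subset.
* **PPV.** We estimate the relative PPV
  $\mathrm{rPPV} = \widehat{\mathrm{PPV}}_A / \widehat{\mathrm{PPV}}_B$ and
  test $\log \mathrm{rPPV} = 0$ with a delta-method variance. The eight
  cells of the (flag A, flag B, outcome) cross-classification are one
  multinomial; propagating the gradient of
  $\log n_{AD} - \log n_A - \log n_{BD} + \log n_B$ through its covariance
  gives $\widehat{\mathrm{Var}} = \sum_j m_j g_j^2$ (the gradient has zero
  multinomial mean), which accounts for the overlap of the two flagged
  sets. Tests validate this against a paired nonparametric bootstrap; the
  two agree closely once each flag has a few dozen true-positive calls,
  which is where a first-order method should be trusted.

These two statistics are our concrete choice of paired-design comparisons
for the star annotations (`*` p < .05, `**` p < .01, `***` p < .001); all
computation is at full precision, rounding only at the formatting layer,
with half-up percentage rounding in reports.

`stratified_summary()` computes both flags' metrics, the practice-minus-
algorithm delta and the paired p-values per stratum and outcome, keeping
empty strata as flagged rows. `across_strata()` collapses to
average-(range) rows; strata are weighted equally by default (an
unweighted mean across practices), with `weight = "patients"` as the
alternative, since which weighting the "average (range)" presentation
uses is not fixed by convention.

## The synthetic population

No real panel ships with the package, so `generate_population()` draws one
with the causal structure the analysis assumes:

* **Latent severity.** $\lambda \sim \mathrm{LogNormal}(0, 0.9)$. A latent
  positive severity with a heavy right tail is the simplest device that
  simultaneously concentrates cost and induces realistic correlation
  between conditions and utilization.
* **Demographics.** 57% female; age normal with mean 60.3 and SD 17.5
  years, truncated to [18, 102) — an adult panel with realized mean age
  near 61.
* **Conditions.** Each condition is Bernoulli with logistic probability in
  $\log\lambda$; the intercept is solved by root-finding on the realized
  severity draw so marginal prevalences hit their targets (diabetes 11%,
  neoplasm 11%, heart disease 10%, psychiatric 8%, lung 5%, plus rarer
  severe variants that exercise the dominance rules). Codes come from a
  toy vocabulary of 2-4 codes per condition.
* **Utilization.** ED and hospitalization counts are gamma-frailty Poisson
  (negative binomial) with rate $\mathrm{base}\cdot e^{\beta \log
  \lambda}$; the same person-level rate generates the prior and follow
  year, which induces year-to-year correlation (about 0.65 for ED counts)
  without an explicit autocorrelation parameter. Expenditures are a
  log-normal base cost (person effect shared across years, year-specific
  noise) plus $900 per ED visit and $13,000 per hospitalization.
* **Payer and retention.** About 10% of patients are medicare or dual
  eligible — the subset treated as having reliable outcome feeds — with
  97% seen prior to stratification and 3% attrition, so the cohort
  filters have work to do.
* **Practice tiering.** `simulate_practice_tiers()` implements three
  stylized workflows: *intuition* tiers $\log\lambda$ plus
  $N(0, \sigma^2)$ noise with $\sigma = 2$ by default (clinicians see true
  risk, imperfectly — how intuition differs informationally from an
  algorithm is not observable, so this noise parametrization is a modeling
  choice, with $\sigma$ exposed); *algorithm* tiers the HCC-style score
  computed from observed codes only; *adjudication* starts from the
  algorithmic tier and, with probability 0.7 by default, a reviewer
  corrects it to the latent-severity tier. The defaults make adjudication
  clearly outperform intuition in top-tier sensitivity, the qualitative
  contrast the evaluation is designed to detect.

The default configuration is calibrated, at $n = 40{,}000$, to reproduce
the margins of the panel it emulates: follow-year ED $\ge 1$ near 30%, ED
$\ge 2$ near 12%, hospitalization $\ge 1$ near 14%, expenditures
$\ge \$30{,}000$ near 9%, a toy-score median near 0.60 with IQR near
(0.28, 0.80), and the top decile of patients carrying roughly two thirds
of spend.

What the generator does **not** emulate: care-management feedback on
follow-year outcomes (an acknowledged confounder in real panels),
realistic claims billing or code-frequency distributions, dated event
streams (it emits pre-aggregated yearly counts, since the analysis uses
aggregates with the stratification date as day 0 and windows of
$[-365, 0)$ and $[0, 365)$ days), or multi-practice heterogeneity within
one draw — a "study" is a list of per-practice generator configurations,
as in `default_practices()`. Passing tests on synthetic data therefore
show the machinery is correct under the assumed data-generating process,
not that any particular real panel behaves this way.

## Numerical choices and degenerate inputs

* Tier fitting requires at least 4 distinct scores; heavier degeneracy is
  an error, not a silent collapse.
* The exact/asymptotic switch for the paired sensitivity test is a
  discordant total of 25.
* Undefined quantities (zero denominators, single-class outcomes, nobody
  flagged) propagate as `NA` with a warning; reports show blank cells.
* Kappa returns 1 for unanimous tables (degenerate marginals with perfect
  agreement).
* All randomness flows from integer seeds; child seeds derive
  deterministically, so `run_study()` is byte-reproducible given its
  configuration.

## Problem sizes used by the test suite

Calibration checks run one draw at $n = 40{,}000$; qualitative
mode-ordering checks use $n = 20{,}000$; type-I error of both paired tests
is estimated from 2,000 null replicates of 1,000 patients each and
required to land in [0.03, 0.07] at $\alpha = 0.05$; oracle equivalence
suites use 200-500 random tables and exhaustive enumeration where the
space is small (all $2^6$ category subsets, all discordant splits up to
20). These sizes keep Monte-Carlo error well inside the tolerances being
asserted.

## A short example

```{r example, eval = FALSE}
library(riskstrat)

report <- run_study(study_config(
  practices = default_practices(n_per_practice = 3000, seed = 1),
  seed = 1))
report$agreement
subset(report$metrics, metric == "sensitivity")
mean_delta_difference(report$metrics, "sensitivity",
                      "adjudication", "intuition")
```

## Known limitations

* The toy model's discreteness means tier sizes on algorithmic scores can
  deviate from targets by a couple of percentage points where a tie block
  straddles a boundary; real coefficient sets are nearly continuous.
* The delta-method PPV test is first-order; with very few true-positive
  calls per flag its p-values drift from the bootstrap's, and the
  discordant-pair exact test is the safer primary comparison there.
* Single-score confidence intervals and multivariable recalibration are
  out of scope.
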