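---
title: "Validating a dichotomous screening scale: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a dichotomous screening scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenval)
```

`screenval` evaluates a 26-item yes/no screening instrument against a
gold-standard criterion: reliability, factorability, criterion validity
(ROC), and a decision-theoretic choice of the screening cut-off. This
vignette explains the statistical machinery, the synthetic-data model that
stands in for subject-level data, and the design choices made where
conventions genuinely diverge.

## The data and the scoring model

The pipeline's universal input is a subjects-by-items binary matrix: 26
scale items coded 1 for a symptom-endorsing "yes", plus either a block of
gold-standard criterion items (a structured clinical checklist) or a
precomputed diagnosis flag. The total score is the plain count of endorsed
items (0–26); per-factor scores count within a user-supplied item-to-factor
partition. The instrument family's classical four factors (compulsive
behavior, functional impairment, withdrawal, and a 3-item tolerance factor)
ship as an editable default map, reconstructed rather than authoritative —
validation reports for the dichotomous adaptation do not print the
assignment.

Two diagnosis paths are supported because validation studies use both: a
threshold rule (diagnosed when the criterion count reaches `k`) and a
pass-through column (a clinician's judgement). The reader is strict: any
cell outside {0, 1} aborts with the subject and item named, and empty cells
are errors unless the caller explicitly opts into dropping incomplete
subjects.

## Reliability and validity statistics

**KR-20.** Internal consistency for binary items,
$\mathrm{KR20} = \frac{k}{k-1}\left(1 - \frac{\sum_i p_i(1-p_i)}{s^2_{tot}}\right)$,
the dichotomous special case of Cronbach's alpha. Published reports rarely
state the variance denominator; the default is the sample convention
(`n − 1`, matching `var()` and most software), with a population-variance
switch. Item variances always use the same denominator as the total, which
is what makes KR-20 equal the covariance-form alpha identically — a
property the test suite checks to 1e-10 on random matrices. Zero
total-score variance raises an explicit "undefined reliability" error
rather than returning NaN.

**ICC.** Test–retest agreement of total scores from the two-occasion ANOVA
decomposition. The default is the two-way random-effects,
absolute-agreement, single-measure form
$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$,
because a retest design treats both occasions as interchangeable
measurements and an occasion-level shift should count against agreement.
Consistency and one-way variants are selectable: published ICCs often omit
the model, and the three differ when occasion means drift. The F statistic
reported alongside is $MS_R / MS_E$ (between-subjects over residual), with
its ANOVA p-value. Interpretation bands (≤0.40 poor, ≤0.60 moderate,
≤0.80 good, else excellent) are attached to every correlation-type
coefficient in the report.

**Convergent validity.** Spearman's rho as the Pearson correlation of
mid-ranks — average ranks are the right tie treatment for heavily tied
integer scores. P-values use exact enumeration for small untied samples
and the t-approximation otherwise.

**Design sample size.** The Fisher-z calculation
$n = \lceil ((z_{1-\alpha/2} + z_{power})/\mathrm{atanh}\,\rho)^2 + 3 \rceil$
for a two-sided test of zero correlation; the ceiling is taken because a
fractional subject cannot deliver the stated power. At ρ = 0.60,
α = 0.05, power = 0.90 this gives 25 subjects per group.

## Factorability of binary items

Before any factor model is entertained, the correlation matrix must show
common structure. Two matrices are available:

* **Phi** — Pearson correlation of the binary columns; the default, since
  it is what most general-purpose software computes for KMO/Bartlett.
* **Tetrachoric** — the latent bivariate-normal correlation, estimated by
  maximum likelihood from each pair's 2×2 table with thresholds fixed at
  the observed margins. The bivariate normal CDF is computed by 1-D
  reduction ($\int_{-\infty}^{h}\phi(x)\Phi\!\big((k-\rho x)/\sqrt{1-\rho^2}\big)dx$
  via adaptive quadrature) and the likelihood maximised on (−0.999, 0.999).
  A 0.5 continuity correction is applied to all four cells only when a
  zero cell occurs (or an error is raised if smoothing is disabled).
  Matrices assembled pairwise need not be positive definite, so an
  eigenvalue-clipping repair (`nearest_psd()`, warning attached) runs
  before inversion-based statistics.

**KMO** is the ratio of summed squared correlations to that sum plus the
summed squared anti-image partial correlations from the matrix inverse.
The formula value is always returned; the `factorable` flag uses the
conventional 0.6 minimum-adequacy bar rather than the 0.5 no-structure
boundary, so that a matrix indistinguishable from the identity (KMO
numerically at 0.5) is flagged unfactorable instead of squeaking past on a
rounding error. **Bartlett's sphericity** is
$\chi^2 = -(n-1-\tfrac{2k+5}{6})\ln\det R$ on $k(k-1)/2$ degrees of
freedom. An exploratory one-factor solution is extracted by iterated
principal axis: communalities start at squared multiple correlations and
the leading eigenvector is re-estimated until the largest communality
change falls below `tol` (default 1e-8, capped at 200 iterations; on
non-convergence the error carries the last iterate). Confirmatory models
for categorical data (WLSMV and its fit indices) are deliberately not
implemented — that estimation belongs to dedicated SEM software; this
package supplies the exploratory checks that precede it.

## ROC and the decision-theoretic cut-off

With integer totals, the ROC has one operating point per cut-off
0 … 27, a subject screening positive at `total ≥ cutoff` — the screening
orientation, under which low cut-offs are sensitive and high cut-offs
specific. The trapezoidal AUC over (1 − specificity, sensitivity) then
equals the tie-corrected Mann–Whitney statistic
$P(S_1 > S_0) + \tfrac12 P(S_1 = S_0)$ exactly, which the tests verify by
brute-force pair counting. The standard error is Hanley–McNeil (the
single-SE convention of validation reports); a DeLong-style alternative
was judged out of proportion for a pipeline whose inference is descriptive.

Prevalence-free properties are carried to a target population by Bayes:
$PPV = \pi se / (\pi se + (1-\pi)(1-sp))$, $NPV$ symmetrically, and
$accuracy = \pi\,se + (1-\pi)\,sp$; 0/0 predictive values return `NA` with
the convention documented. The expected relative cost of screening at an
operating point is
$C_{TP}\,\pi se + C_{FN}\,\pi(1-se) + C_{TN}(1-\pi)sp + C_{FP}(1-\pi)(1-sp)$,
with default weights (0.89, 0.001, 0.03, 1.0) — the mental-health screening
cost proportions in which a missed case costs most and a correct
reassurance is nearly free. The optimal cut-off minimises this cost over
all 28 operating points; ties break toward the lower cut-off because a
screening instrument favours sensitivity (a message notes the tie). The
`metrics_table()` grid (default prevalences 5%, 10%, 20%, 35.66%, 40%)
reproduces the supplementary-table layout of validation reports, with the
per-prevalence optimum flagged.

## The synthetic cohort generator

No subject-level data ship with the package; a seeded generator emulates
the structure the analysis assumes:

* one latent severity trait $\theta \sim N(0,1)$ per subject;
* 26 Bernoulli items with 2PL probabilities
  $\mathrm{logistic}(a_i(\theta - b_i))$ — the simplest generative model
  consistent with a unidimensional scale of graded items;
* a criterion count Binomial$(K, \mathrm{logistic}(a_c(\theta - b_c)))$
  and diagnosis at `count ≥ threshold`, giving a gold standard correlated
  with, but not determined by, the scale;
* retest responses regenerated from
  $\theta' = s\theta + \sqrt{1-s^2}\,\varepsilon$, so the `stability`
  parameter is the latent test–retest correlation and item-level
  disagreement between occasions occurs naturally.

Defaults: discriminations evenly spaced on [0.8, 2.0] (weak to strong
items), difficulties on [−1.5, 1.5] (items informative across the trait
range), K = 9 criterion items with diagnosis at 5 — a realistic
operationalisation of a structured criteria checklist, configurable
because validation reports typically omit the exact rule — and the
criterion difficulty solved by quadrature so the population prevalence is
35.66%, the prevalence regime the pipeline's default grid centres on.
Randomness uses one master seed split into deterministic sub-streams per
array, with each subject occupying a contiguous block, so cohorts are
bit-reproducible and enlarging a cohort never perturbs earlier subjects.

`theoretical_auc()` is the generator's recovery oracle: the exact AUC of
the total score against the diagnosis, computed from the Poisson-binomial
score distribution conditional on diagnosis via quadrature over θ (2001
trapezoid nodes on [−8, 8], accurate far beyond Monte-Carlo resolution).
Tests require empirical cohort AUCs to match it within Monte-Carlo error,
and the default parameters yield a theoretical AUC of about 0.94 —
a strongly discriminating scale.

What the generator does **not** emulate: multidimensional structure,
differential item functioning, response styles, missingness (the emulated
design had none), or clinician-judgement diagnoses that deviate from the
count rule. Passing recovery tests therefore show the pipeline's
statistics are computed correctly, not that any particular real
instrument has these properties.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at the study's own scale —
cohorts of 415 subjects with 130 retested, 100-seed recovery loops, 200
random decision-problem fixtures — chosen to mirror the design the
pipeline targets while keeping a full run in the order of seconds to a few
minutes. Other conventions collected in one place: tetrachoric likelihood
bracketed at |ρ| ≤ 0.999; probability floors at 1e-12 inside likelihoods;
cost-tie tolerance 1e-12; PSD repair floor 1e-8; the `uniroot` solving the
default criterion difficulty runs to 1e-10 on [−4, 4]. Percentages are
displayed to 2 decimals in rendered tables while every internal
computation is full precision.

## Worked example

```{r example, eval = FALSE}
params <- default_irt_params()
path <- tempfile(fileext = ".csv")
simulate_to_csv(params, 415, seed = 2026, path,
                retest_n = 130, stability = 0.95)
report <- run_pipeline(path, pipeline_config(fmap = default_factor_map()))
print(report)
write_report_json(report, "report.json")
```

## Known limitations

* Analytic standard errors only; no bootstrap confidence intervals.
* The dichotomous format is assumed throughout — no Likert scoring, no
  polychoric correlations, no ordinal alpha/omega.
* The one-factor extraction is exploratory; it orders items by loading but
  fits no confirmatory model and reports no fit indices.
* Tetrachoric estimation is pairwise-ML; a full multivariate estimate
  (and hence a guaranteed-PSD matrix) is out of scope.
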