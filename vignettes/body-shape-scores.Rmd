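---
title: "Quantitative body-shape scores and hypertension: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative body-shape scores and hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsspm)
```

## The problem

Single obesity indices — body-mass index (BMI), waist circumference (WC),
waist-to-hip ratio (WHR), waist-to-stature ratio (WSR) — each capture either
the amount of body fat or a single aspect of its distribution, and none
dominates the others as a predictor of hypertension. `bsspm` implements a
quantitative *body-shape score* (BSS): a latent variable extracted from
several anthropometric measurements at once by partial least squares path
modeling (PLSPM), together with the machinery needed to evaluate it — a
bootstrap test of the body-shape → blood-pressure path, a type-I-error and
power simulation, ROC/AUC comparison against the single indices, and a
nine-type body-shape taxonomy (BMI bands × sex-specific WHR bands) against
which the score's monotone trend can be checked.

Because the underlying survey data is not redistributable, the package is
driven entirely by a synthetic cohort generator calibrated to the published
sex-specific summary statistics (means, SDs, and the correlation matrix over
BMI/WC/WHR/WSR/Hip) — every analysis in this package runs end-to-end without
any access-restricted input.

## The model

Each model couples latent variables through directed inner paths:

* $\xi_1$ — the body-shape score, measured reflectively (Mode A) by its
  manifest block: BMI/WC/Hip for BSS1, BMI/WC/WHR/WSR for BSS2, or a single
  index for the four single-indicator variants;
* $\xi_2$ — the blood-pressure score (BPS), fed by a single manifest, the
  binary hypertension indicator (SBP ≥ 140 mmHg, DBP ≥ 90 mmHg, or current
  antihypertensive medication);
* $\xi_3$ — age, a single-indicator latent with its own path into $\xi_2$.

Estimation follows Lohmöller's alternating algorithm: (1) *outer step* —
each latent score is the standardized weighted sum of its own standardized
manifests; (2) *inner step* — each latent gets a proxy built from adjacent
latent scores (path scheme by default: regression weights for predecessors,
correlations for successors; centroid and factorial are selectable);
(3) *Mode A update* — each manifest's outer weight is set proportional to
its covariance with the block proxy. Iteration stops when the largest
absolute outer-weight change drops below `1e-7` (at most 300 iterations;
non-convergence is an error, never a silent result). Afterwards the path
coefficients $\beta$ are OLS coefficients of each outcome latent on its
standardized predecessors — so for single-indicator blocks they reduce
exactly to Pearson/standardized-OLS coefficients, which is the oracle the
test suite checks against — and the loadings $\lambda$ are manifest–score
correlations.

PLS scores are sign-indeterminate; every block has an anchor manifest (BMI
for body-shape blocks, the hypertension flag for BPS, age for AGE) with
which its score is constrained to correlate nonnegatively. The same rule is
applied inside every bootstrap refit, which keeps resampled parameters on a
common orientation before a standard error is computed.

The significance of a parameter $w$ is assessed with the normal test
$U = |w - 0| / \mathrm{se}(w)$, where $\mathrm{se}(w)$ is the bootstrap
standard error over subject resamples (default $B = 500$ for data analyses,
$B = 200$ inside simulation replicates, both configurable; the normal
interval $w \pm 1.96\,\mathrm{se}$ is reported as primary — the published
intervals are symmetric around their estimates — with the percentile
interval alongside).

## The synthetic-data generator

`build_default_moments()` carries, per sex, the published means and SDs of
age, SBP, DBP, height, weight, Hip, WC, BMI, WHR and WSR, and the published
correlation matrix over {BMI, WC, WHR, WSR, Hip}. Four quantities are *not*
published and carry package defaults flagged as assumptions: Hip–WHR
correlation (0.15 male / 0.10 female), Hip–WSR (0.60), all age–anthropometry
correlations (0), and the SBP–DBP residual co-movement (0.5). The male
matrix assembled from the printed pairwise values is slightly indefinite
(smallest eigenvalue ≈ −0.005); `psd_repair()` clips eigenvalues at `1e-8`
and re-normalizes to unit diagonal, announcing itself whenever it acts.

The simulation's data-generating process mirrors the study design:

1. a population (default 500,000 subjects) of {BMI, WC, Hip} is drawn
   multivariate-normally from the calibrated moments — height and weight are
   not simulated, the indices are the primitives;
2. blood pressure is attached on the standardized scale,
   $\mathrm{SBP}_z = \delta\,\mathrm{BMI}_z + \varepsilon$ with
   $\varepsilon \sim N(0, 1-\delta^2)$, then mapped affinely to the SBP
   mean/SD, so marginal BP moments are preserved for every $\delta$ and
   $\mathrm{corr}(\mathrm{BMI}_z, \mathrm{SBP}_z) = \delta$ by construction.
   The effect grid $\delta \in \{0.10, \dots, 0.30\}$ brackets the published
   standardized SBP-on-BMI slope of 0.325. The DGP does not specify a
   separate DBP mechanism; we apply the same $\delta$ to DBP with an
   independent noise stream (sharing the 0.5 residual correlation) — a
   symmetric-treatment choice, exposed rather than hidden, since the
   hypertension flag depends on both pressures;
3. per replicate, a simple random sample of size $n \in \{500,\dots,2500\}$
   is drawn without replacement, the BSS1 model is fitted, and the
   body-shape path is tested by the bootstrap U test. The simulated data
   carries no age variable, so the fitted simulation model is the BSS1 →
   BPS structure without the age latent.

For analysis-shaped cohorts, `generate_cohort()` additionally draws age
(Gaussian, so the load-time eligibility filter at 18 years trims about 5% of
rows) and WHR/WSR, and uses $\delta = 0.325$ by default; the fitted BP block
uses the binary flag, matching the real-data choice, with continuous SBP
available via `model_catalog(bp_manifest = "sbp")` for sensitivity runs
(that switch is how the test suite checks that the single-index path
coefficient recovers $\delta$ itself).

**What the generator does not emulate.** Real anthropometrics are skewed,
age-correlated, and linked to blood pressure through more than BMI; the
generator is Gaussian, age-independent, and drives BP through BMI alone. Two
consequences are worth stating plainly. First, on synthetic cohorts the
single BMI index tends to carry the *largest* path coefficient and AUC —
composite scores dilute the one true signal with correlated noise — whereas
on the real survey data the composite BSS1 was reported strongest. Passing
tests here validate the estimator and the pipeline, not the substantive
superiority of BSS1, which only real data can show. Second, group-mean
shifts between hypertensive and normotensive subjects arise implicitly from
the BMI link (and can be checked against printed two-group tables with
`point_biserial_from_groups()`), not by explicit calibration.

## Numerical and design choices

* **Interval conventions.** All classification bands (BMI <24 / 24–28 / ≥28;
  WHR <0.85 / 0.85–0.90 / ≥0.90 for men, <0.80 / 0.80–0.85 / ≥0.85 for
  women) are half-open `[lower, upper)` with the top band closed below,
  mirroring the "≥" notation of the published table.
* **Missing medication flag** is treated as "no" in the outcome definition;
  listwise exclusion (the study's approach) is a separate, explicit
  `filter_complete()` step so the two concerns cannot interact silently.
* **Standardization** uses the n−1 denominator everywhere; constant columns
  are rejected by name.
* **Initialization** of outer weights is all-ones; with well-conditioned
  blocks the fixed point does not depend on it.
* **Inner scheme.** The original software's scheme is not stated; the path
  scheme is the default of PLS-SEM software of that era and all three
  schemes are selectable. For these model shapes (single endogenous latent)
  the converged path coefficients agree across schemes.
* **Ties in ROC curves** count one half, the rank-statistic convention; AUC
  comparisons between indices use the DeLong paired test.
* **Protected LSD.** Pairwise least-significant-difference comparisons are
  only declared significant when the omnibus F is significant at 0.05; no
  further multiplicity correction, matching the named procedure.
* **Seeds.** Every stochastic function takes an explicit integer seed; the
  simulation derives per-cell and per-replicate sub-seeds deterministically
  (all below $2^{31}$), so any single replicate can be replayed in
  isolation.
* **Score scale.** Published group summaries report BSS1 on roughly a 48–52
  scale and BSS2 near 1.1–1.2; the defining rescaling is not stated.
  `compute_bss()` returns the standardized score and offers an affine
  rescale for presentation, with no claim of reproducing those scales.

## Problem sizes used by the tests and scripts

The acceptance computation runs the full null design (population 500,000,
1000 replicates of $n = 2000$, $B = 200$) in about three minutes. The test
suite exercises the same machinery at a 200-replicate profile with
correspondingly widened binomial bands, the power comparison on the corner
grid $\delta \in \{0.10, 0.30\} \times n \in \{500, 2500\}$ with 200
replicates, and the remaining properties on cohorts of a few hundred to a
few thousand subjects. The `analysis/` drivers use the full published
stratum sizes (6,939 men, 8,233 women) and a reduced simulation grid.

## Known limitations

* Under the null, the anchored path coefficient of a *multi-manifest* body
  block is not Gaussian: its outer weights are driven by noise, making the
  coefficient a signed norm-like statistic with little mass near zero. The
  normal U test is therefore mildly anti-conservative there (most visibly
  at the 1% level), and rejection rates vary between simulated populations
  beyond binomial noise because all replicates share one fixed population.
  The package reports what it measures; single-indicator models do not show
  this effect, and the `test = "ols"` switch provides an independent
  normal-theory cross-check.
* Mode B (formative) measurement is not implemented; goodness-of-fit
  indices (GoF, SRMR) are out of scope, as is any survey-weighting or
  longitudinal structure.
* Whether the published AUCs were computed on an age-adjusted predictor or
  on the raw score cannot be determined from the text; `run_analysis()`
  reports the age-adjusted predictor's AUC and the raw score is one
  `compute_bss()` call away.
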