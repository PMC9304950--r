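---
title: "Models and methods in twinwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twinwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinwaves)
```

twinwaves implements the analysis battery used in longitudinal twin
studies of mental health across repeated assessment waves — a
pre-pandemic baseline plus pandemic-era follow-ups being the motivating
design. This vignette explains the models, the tunable parameters and
their defaults, the synthetic cohort generator and what it does and does
not emulate, and the numerical choices made where the design was
genuinely open.

## The synthetic cohort generator

Real twin-cohort data of this kind are access-restricted, so the package
ships a generator whose defaults encode the study conditions every
downstream stage assumes:

* **Pair counts.** 1,501 MZ and 2,380 DZ complete pairs — the scale of a
  national twin registry wave in the relevant age band.
* **Variance components.** Standardized (a², c², e²) = (0.33, 0.07,
  0.60) at every wave: heritability around a third, small shared
  environment, nonshared environment (including measurement error)
  carrying the rest.
* **Cross-wave structure.** Compound-symmetric latent correlations:
  rA = 0.95 (genetic effects nearly the same factor throughout),
  rE = 0.41 (moderately persistent person-specific environment). The
  shared-environment correlation defaults to 0.90; with c² ≈ 0.07 it is
  weakly identified and nothing downstream is sensitive to it.
* **Mean structure.** A mean elevation of 0.14 s.d. from wave 2 onward
  (the pandemic-onset shift), and a sex mean difference of 0.35 s.d.
  (about 3% of variance), applied symmetrically so the phenotype variance
  stays at 1 up to a δ²/4 term.
* **Measures.** Eight symptom scales with cross-measure latent
  correlation 0.40 at all three levels (A, C and E), so phenotypes
  intercorrelate 0.40 and the baseline first principal component explains
  roughly (1 + 7·0.40)/8 ≈ 47% of variance — a typical p-factor share for
  a symptom battery. This value is a package choice; the generating
  studies do not publish one number for it.
* **Ages** uniform on 21–25; MZ pairs share sex, DZ co-twin sexes are
  independent coin flips (equivalently: same-sex with probability one
  half). Opposite-sex DZ pairs are not modelled separately.

Per family, the latent A, C and E factor vectors over measures × waves
are drawn jointly from the Kronecker covariance (pair relatedness ⊗
cross-measure ⊗ cross-wave), which makes the population within- and
cross-twin covariances exact by construction: the MZ/DZ intraclass
correlations converge to a² + c² and ½a² + c², and the cross-wave
phenotypic correlation to √(a²ᵢa²ⱼ)rAᵢⱼ + √(c²ᵢc²ⱼ)rCᵢⱼ + √(e²ᵢe²ⱼ)rEᵢⱼ.

Attrition is wave-level nonresponse from wave 2 on, either MCAR or MAR
with retention logit lowered by `mar_slope` per s.d. of the baseline mean
score; real cohorts do not publish their missingness mechanism, so both
are offered and neither is claimed to match any particular study.
Latent trajectory classes add per-wave mean offsets to every measure;
the true class labels and baseline genetic factor scores live in a
sidecar table (`cohort_truth()`), never in the analysis-facing CSV, so
recovery tests cannot leak truth. Polygenic scores are built as
`cor · A + √(1−cor²) · U` with U twin-structured, which yields exactly
the stated correlation with the baseline genetic factor, identity within
MZ pairs, and 0.5 correlation within DZ pairs. A skew option
(exponential transform, re-standardized) exists but is off by default;
the analyses are designed for untransformed scores.

**What passing tests do not show.** The generator is multivariate normal
with linear mean structure. Real symptom scales are bounded, skewed and
ordinal-ish; real attrition is not a clean logit; real class structure is
fuzzier than a Gaussian mixture. Recovery of generating values here
validates the estimators' correctness, not their robustness to those
violations.

## Preprocessing

Scores are residualized on sex and age by per-measure-wave OLS and
standardized, because co-twins share age exactly and MZ co-twins share
sex — uncorrected, this inflates shared-environment estimates. One
pooled regression per measure-wave is used (not per zygosity group), and
residuals are standardized within wave on the full observed sample.
Rows with a missing covariate are excluded from the fit but still
receive a residual where possible. Downstream twin models therefore see
mean-0, s.d.-1 scores, which is also why the models equate means across
twins and zygosity groups.

## The covariance-structure engine

All SEM-type models go through one multigroup engine: a model maps a
named, box-constrained parameter vector to per-group implied mean
vectors and covariance matrices; the FIML deviance sums each row's
multivariate-normal log-density restricted to its observed variables,
with rows grouped by missingness pattern (all-missing rows contribute
zero). Minimization is L-BFGS-B from documented start values plus seeded
jittered restarts (5 by default); convergence requires the optimizer's
own flag plus a numerical gradient-norm check, and failures are flagged,
never silent. A non-positive-definite implied covariance returns a large
finite penalty, steering the optimizer back without crashing it.

Numerical choices: relative deviance tolerance 1e-10 passed to the
optimizer, gradient tolerance 1e-3 scaled by sample size, penalty 1e10.
Variance positivity is enforced by estimating paths (Cholesky-style)
rather than variances, which avoids boundary pathologies and matches
twin-SEM convention. Confidence intervals are likelihood-based: the
profile deviance is bisected to where it rises by the χ²(1) quantile;
bounds that hit a box constraint are reported at the constraint and
flagged boundary-censored. The interval for a standardized component
squares the path bound and divides by the fitted total variance — on
standardized scores the total variance is tightly determined, and the
coverage simulation in the test suite confirms ≈95% coverage. A
bootstrap alternative was considered and not implemented; the likelihood
intervals are standard for this model class.

## Twin models

`fit_univariate_ace()` is the two-group model with MZ covariance
a² + c², DZ covariance ½a² + c², a common mean, and FIML over pairs with
a missing co-twin. Standardized components are squared paths over total
variance and sum to 1 by construction. Falconer moment estimates are
reported unconstrained (negative values warn) — the SEM estimates are
the authoritative constrained ones.

The multivariate model comes in two likelihood-equivalent
parameterizations, both fitted on the wide pair layout over waves:

* **Correlated factors:** per-wave a, c, e paths plus cross-wave factor
  correlations (bounded in (−1, 1); inadmissible combinations are
  rejected through the implied-covariance penalty). This yields rG, rC,
  rE directly and supports profile CIs on the correlations (on by
  default only for bivariate fits, where it is cheap).
* **Cholesky:** lower-triangular paths per factor, diagonal entries
  non-negative for identification. The innovation proportion at wave w —
  the squared diagonal over the row sum of squares — is the share of
  that factor's variance at w independent of all earlier waves; under a
  near-unit rA it is near zero, the "no new genetic variance" signature.

The equality of the two deviances on any dataset is asserted in the test
suite; it is the strongest internal consistency check the twin module
has. Joint fits over all five waves are supported (the parameter count
grows as 3·W(W+1)/2 plus means); the acceptance experiments use the
bivariate model, which is what the headline cross-wave correlations
refer to. No sex-limitation or gene–environment interaction models are
included, and "reliable variance" corrections are deliberately absent:
e² includes measurement error.

## Latent profiles

`fit_lpa()` is an EM for a Gaussian mixture with diagonal covariance and
variances equated across classes but free across waves — the reading of
"variances equated, covariances fixed to 0" that matches the default of
the mixture software family this model descends from. Initialization is
k-means with seeded restarts (20 by default); runs that collapse a class
below one expected member are discarded; ties go to the best final
log-likelihood, then the lower class count. Classes are canonically
ordered by wave-1 mean. Entropy is the normalized posterior entropy
(1 = perfect separation). Model selection uses BIC =
−2lnL + p·ln n with p = kW + W + (k−1); single imputation of missing
waves (`impute_single()`: FIML moments, one seeded conditional draw) runs
once before all class counts, so every k sees the same data. A known
divergence: on real data of this kind, fit indices often drift toward
many small, weakly separated classes; BIC on well-separated synthetic
mixtures selects the
generating k, and the package reports the full fit table so a user can
apply a different criterion.

## Growth curves

`fit_lgc()` fits intercept + slope (+ quadratic) factors with loadings
fixed to time codes, freely correlated factors and heteroscedastic
residuals (free per wave, because a disruption concentrated at wave 2
makes homoscedasticity implausible), by FIML. Default time codes are
years since baseline, 0, 2.0, 2.25, 2.5, 2.92 — a 2018 baseline and
April/July/October 2020 and March 2021 waves; no canonical coding
exists for such a design, and all deviances are invariant to affine
recoding
(estimates transform accordingly; asserted in tests). The
slope-variance LRT fixes all slope (co)variances to zero (df 2 for
linear); with one pre-disruption wave a piecewise model is not
estimable, so shapes are linear and quadratic only. Residual variances
that hit zero are reported as Heywood annotations rather than errors.

## Association analyses

The p-factor is the first principal component of the column-standardized
complete-case matrix, sign-fixed so the mean loading is positive, scores
standardized. Polygenic prediction is the incremental R² of the score
over covariates in OLS (equal to the squared partial correlation times
1 − R²base, asserted in tests), with an optional permutation p-value;
use one twin per family for unrelatedness. Extreme groups are strict
±1 s.d. tails of the standardized score — boundary values fall in the
middle, a documented tie-break choice. The per-wave
high-vs-low contrast uses the same pooled-s.d. Cohen's d as the
descriptive module, and the group×time interaction reuses the MANOVA
machinery. The truncated-normal identities (tail gap 2φ(1)/Φ(−1) ≈ 3.05
s.d., truncated variance ≈ 0.199) serve both as test oracles and to
invert a target wave-2 gap into a generating link coefficient in
`simulate_extremes_cohort()`.

Cohen's d throughout is the two-sample, n-weighted pooled-s.d. form
rather than a paired form, because attrition makes wave samples only
partially overlapping; d² / (d² + 4) converts to proportion of variance.
The repeated-measures MANOVA tests time and time×sex on
successive-difference contrasts via Wilks' Λ with Rao's F approximation
(effect-coded sex, so the time test targets the unweighted grand mean,
as mainstream GLM software does), and the between-subject sex effect as
the univariate ANOVA on the per-person wave mean; partial η² is
1 − Λ^(1/s). MANOVA is complete-case — classical MANOVA has no
missing-data mechanism — and the dropped-row count is attached to the
result.

## Problem sizes and reproducibility

The simulation experiments in the test suite and acceptance script use
cohorts of 1,500 MZ + 2,380 DZ pairs for twin-model recovery (20
replicates), n = 3,000–4,000 unrelated individuals for the descriptive,
profile and extremes experiments, and smaller cohorts (a few hundred
pairs) for property checks and the CI coverage simulation — sizes at
which each experiment completes in seconds to a few minutes on one CPU
while keeping Monte-Carlo error well inside the asserted tolerances.
Every stochastic function takes an explicit seed; the same configuration
and seeds give byte-identical cohorts and pipeline summaries.

## Known limitations

Multivariate normality everywhere; no ordinal/threshold models and no
weighted least squares. No sex-limitation, gene–environment interaction,
common-pathway or direction-of-causation twin models. The LPA has no
bootstrap likelihood-ratio test for k. Polygenic scores are continuous
stand-ins with the right correlation structure, not genotype-derived.
The generator's attrition and class structures are idealizations, and
parameter-recovery results should be read as estimator validation, not
as evidence about any real cohort.
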