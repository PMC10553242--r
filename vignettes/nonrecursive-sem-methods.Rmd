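---
title: "Methods: non-recursive SEM for a student mental-health survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-recursive SEM for a student mental-health survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semloop)
```

## The model and its assumptions

`semloop` is built around one study design: a cross-sectional survey in
which depressive symptoms and adult ADHD symptoms are latent outcomes
measured by ordinal screeners (PHQ-9, ASRS-v1.1), hypothesized to
influence each other reciprocally, with latent problematic internet use,
insomnia and social support plus ~26 observed covariates as exogenous
predictors. Writing $\eta$ for the latent outcomes and $x$ for all
exogenous predictors,

$$\eta = B\eta + \Gamma x + \zeta, \qquad
y = \Lambda \eta^{*} + \varepsilon,$$

where $B$ contains the reciprocal paths (a *non-recursive* system),
$\zeta$ are disturbances with free covariance, and each construct's first
indicator loading is fixed to 1 to set its scale. The package
parameterizes everything in RAM form — one asymmetric matrix $A$ for all
directed paths, one symmetric $S$ for all variances and covariances, a
filter $F$ selecting observed nodes — with implied covariance
$\Sigma = F(I-A)^{-1}S(I-A)^{-T}F'$. Estimation minimizes the
normal-theory discrepancy
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S_{n}\Sigma^{-1}) - \log|S_n| - p$.

Treating 4- and 5-point ordinal items as continuous in an ML fit is a
fidelity-to-the-workflow choice, not a statistical endorsement; the
bootstrap (`sem_bootstrap()`) is the inferential companion for the
resulting non-normality. Polychoric/WLSMV estimation is out of scope.

## Identification of the feedback loop

A reciprocal system with correlated disturbances is not identified by
counting alone. The package implements both classical checks on the
binary *system matrix* (one row per endogenous equation, one column per
structural variable, 1 = direct effect or own column):

* **Order condition** (necessary): excluded variables per equation
  $K \ge M-1$, with $M$ the number of endogenous equations. In the study
  fixture the ADHD equation excludes the 12 depression-only predictors
  and the depression equation excludes the 3 ADHD-only predictors
  (mother/father education, birth order), so both pass against $M-1=1$.
* **Rank condition** (sufficient): delete the equation's row and every
  column it occupies, then drop zero rows, duplicate rows and rows that
  are sums of other rows; the surviving row count is the rank.
  "Reproducible by adding other rows" is implemented as full linear
  dependence over the rationals (QR rank), which a property test checks
  against an independent rank oracle on thousands of random systems.

`designate_instruments()` returns, for each loop member, *every*
exogenous variable feeding only that member. The study narratively
singles out five instruments for the depression equation; that subset is
an analyst's choice not derivable from the graph, so the package reports
the full candidate set (12 for depression, 3 for ADHD) and the tests
assert the study's named instruments are contained in it.

Free parameters are counted as loadings not fixed for scale, indicator
error variances, structural paths, exogenous variances, disturbance
variances, and declared covariances. For the hypothesized model this
reproduces the planning arithmetic 63 + 24 + 6 + 42 + 5 + 7 = 147, hence
$147 \times 10 = 1470$ and, with 5% non-response inflation rounded
upward, a planned sample of 1544.

## Instrument scoring

Scoring is deterministic and intentionally boring: ASRS items 1–3
dichotomize at "sometimes" (code $\ge 2$), items 4–6 at "often"
(code $\ge 3$), positives at $\ge 4$ flags, with the two-settings
criterion available as an optional AND because item data cannot compute
it; PHQ-9 sums 0–27 with the $\ge 10$ cutoff and the published severity
bands (the unnamed 0–4 band is labelled "none"); ISI, OSSS-3 and PIUQ-9
are arithmetic totals on their published ranges. PIUQ-9 uses its
published 1–5 anchors (totals 9–45). Missing items yield missing scores
— never imputation. Prevalence intervals are Wilson score intervals,
which reproduce the study's printed ADHD band (303/1514 →
20.01%, [18.1%, 22.1%]) where Wald intervals do not.

## The synthetic survey: a stated world

The survey data are not deposited, so `simulate_survey()` generates the
world the analysis assumes. Its defaults are commitments, chosen once:

* **Covariates** follow the study's printed marginal frequencies
  (sex 34.9% female, chronic disease 7.7%, alcohol use 66.5%, year-of-
  study distribution, etc.); counts and hours use rounded normals or
  lognormals matched to printed medians/IQRs. Declared negative
  covariances (insomnia–sleep, mother education–birth order,
  sleep–study) are induced through a Gaussian copula on the generating
  scales, with magnitudes taken from the fitted covariances.
* **Structural coefficients** default to the final-model estimates
  (depression→ADHD 0.73, social support→depression −0.23, insomnia 0.24,
  PIU 0.23, worry 0.24, chronic disease 0.19, ...). Disturbance
  variances are 0.80 (depression) and 0.45 (ADHD), chosen so both latent
  variances land near 1 given the coefficients; the disturbance
  covariance default is 0.10. The generator refuses configurations whose
  loop has eigenvalue stability index $\ge 1$.
* **Measurement**: scale-setting indicators are generated with loading
  exactly 1 — the same convention the estimator fixes — so generated and
  estimated structural coefficients share their units. Remaining
  loadings are fixed values cycling through [0.6, 0.8], typical of
  validated screeners and consistent with the study's reported AVE range;
  error variances give unit-variance items; seven within-construct error
  covariances default to 0.15.
* **Thresholds**: items are discretized on their implied standardized
  scale through fixed per-instrument cutpoints. Equal-probability
  cutpoints would be the neutral default, but they are impossible here:
  they force each PHQ item's expected code to 1.5 and hence near-
  universal screening positivity. The shipped cutpoints are right-skewed
  (symptoms are rare) and were chosen once so that scored outputs land
  near the study's printed figures — ≈21% ASRS-positive, ≈36%
  PHQ-positive, PIU total mean ≈23, OSSS-3 mean ≈9.8 — and are never
  revisited by tests.
* **Latent exogenous correlations** are not printed in the study;
  defaults (PIU–insomnia 0.30, PIU–support −0.20, insomnia–support
  −0.15) are plausible signs and magnitudes, documented as package
  choices.
* **Contamination**: `inject_missing()` blanks one covariate cell for a
  Binomial(n, rate) subset of subjects (the study's regime: ~10 of 1514)
  and refuses rates ≥ 5%, the bound under which listwise deletion is
  defensible. `inject_outliers()` displaces item vectors by 3 SD with
  independent random signs per item. The signs are deliberate: a
  coherent all-items shift lies along the common-factor direction, where
  the Mahalanobis distance of a 3-SD displacement grows by only ~9 and
  is invisible at the $\chi^2_{34}$, $p<0.001$ threshold; sign-scrambled
  displacement is the geometry the screen is designed to catch, and is
  caught at ≥ 90%.

What a green test does establish: the estimator recovers the generating
structural coefficients from data with this covariance structure, at
this sample size, and the workflow's decisions reproduce the study's
printed arithmetic. What it does not: anything about the real survey's
unmodeled features — sampling design effects, item-level
idiosyncrasies, non-MCAR missingness, or the true factor loadings, which
the study does not print.

## Estimation numerics

Starting values: loadings 0.7, variances from the sample diagonal (half
of it for indicator errors), structural paths and covariances 0,
disturbance variances 0.5. Optimization is quasi-Newton (`nlminb`) with
an analytic gradient assembled from
$\partial F/\partial \Sigma = \Sigma^{-1}(\Sigma - S_n)\Sigma^{-1}$
propagated through the RAM structure; a numerical-gradient cross-check
is part of the test suite. Because `nlminb` stops on relative-tolerance
grounds slightly short of a strict gradient criterion, fits finish with
up to five damped Newton polish steps (Hessian by differentiating the
analytic gradient) until the gradient max-norm is below `1e-6`, the
convergence contract; non-converged fits are flagged, never silently
returned. Standard errors come from the observed information,
$\mathrm{Var}(\hat\theta) = \tfrac{2}{n-1}(\nabla^2 F)^{-1}$. Negative
variance estimates are reported and flagged as Heywood cases by default;
`bounded = TRUE` constrains them to zero from below. Non-positive-
definite sample covariances are refused outright.

The baseline model for incremental indices has the closed form
$\chi^2_B = -(n-1)\log|R|$ on $p(p-1)/2$ df. RMSEA's close-fit
probability uses the noncentral chi-square with noncentrality
$0.05^2 \cdot df \cdot (n-1)$. AIC/BIC use the chi-square conventions
$\chi^2 + 2q$ and $\chi^2 + q\log n$; the study's printed AIC/BIC pairs
follow an unstated convention, so comparisons are rank-based, which is
convention-invariant on fixed data.

Modification indices are 1-df score tests: with score $s$ and partialed
information $I_p$ for a candidate fixed cell, $MI = s^2/I_p$ and
$EPC = s/I_p$, standardized to SEPC by the implied SDs of the variables
involved. The score test is a quadratic approximation at the restricted
optimum, so MI matches an actual refit $\Delta\chi^2$ to within ~15% in
the moderate-misspecification regime it is used in, degrading for
gross misspecification; the candidate family defaults to
within-construct error covariances, the modification class the study
workflow allowed.

## Parceling and the pipeline

`parcel_items()` ranks items by absolute standardized loading and deals
them serpentine-style (1,2,3,3,2,1,...) into three parcels (sizes
(3,2,2) for seven items), the parcel score being the item mean; the
published parceling of the study is reproducible through an explicit
assignment argument since its exact item allocation is not printed.
`run_pipeline()` chains scoring → prevalence → diagnostics → listwise
deletion (<5% rule, hard error otherwise) → CFA → parceling →
identification (stopping before any estimation if the rank condition
fails) → four candidate structural models (full; significant-only;
plus error covariances; plus exogenous covariances) → BIC selection
under the RMSEA/CFI/TLI cutoffs → effect decomposition, with bootstrap
percentile intervals (desk-scale default 200 replicates; the study's
3500 is a flag away). Effects use the loop-aware identity
$\mathrm{total} = (I-A)^{-1} - I$; with the study's printed
coefficients this reproduces the depression-mediated indirect effects
(chronic disease 0.19 × 0.73 → 0.14; alcohol 0.10 × 0.73 → 0.07).

## Parameter recovery protocol

The study's data-dependent estimates cannot be reproduced without the
survey; recovery substitutes. Fifty replicates of n = 1500 are generated
at the final-model coefficients and refit by ML. The refits use the
generator's *continuous* indicator records rather than the ordinal
codes: discretizing an item multiplies its covariance with everything
else by the sum of threshold densities, an instrument-specific factor
(~0.84 for the 4-level PHQ items, ~1.28 on the raw 5-level ASRS scale),
so fixed-to-1 scale indicators would place each latent variable on a
different, threshold-dependent scale and the recovered "unstandardized"
coefficients would differ from the generating ones by construction —
a units mismatch, not an estimation defect. On the continuous records
the mean recovered depression→ADHD path is 0.724 (truth 0.73) and
social support→depression −0.233 (truth −0.23) — within Monte-Carlo
error. The ordinal path is exercised separately by the pipeline tests
and by the prevalence/diagnostics checks that operate on scored codes.

## Known limitations

* ML-on-ordinal is biased for thresholds far from the item mean; the
  package mirrors the study rather than fixing this (no polychoric
  machinery).
* Missing data are handled only by the <5% listwise rule; no FIML or
  imputation.
* The bootstrap refits from the point estimates; for near-Heywood data
  sets replicate failures are logged and excluded, with a warning above
  10%.
* Mean structures, multi-group models, and the econometric
  instrument-strength statistics (Cragg–Donald, Stock–Yogo, Sargan) are
  out of scope.
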