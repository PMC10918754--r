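---
title: "Methods: brain signal variability and executive functions across the life span"
author: "boldvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain signal variability and executive functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvar)
```

# The analysis

`boldvar` implements a life-span analysis linking resting-state BOLD signal
variability to executive functions. Its input is a parcellated study: one
ROI-by-time signal matrix per subject (246 regions in five intrinsic
networks — central executive CEN, default mode DMN, salience SN, limbic LN,
dorsal attention DA — plus unassigned regions), a phenotype table
(age 6–85 years, sex, handedness, years of education, mean framewise
displacement), and 14 executive-function task scores per subject.

The pipeline has four stages.

## 1. Signal variability (rMSSD)

Per-ROI variability is the root mean squared successive difference of the
time series,

$$\delta_i = \sqrt{\frac{\sum_{t=2}^{n}(x_{i,t-1} - x_{i,t})^2}{n-1}},$$

with $n$ the number of timepoints; the denominator $n-1$ equals the number
of successive differences, so $\delta_i^2$ is the mean squared successive
difference. Compared with the standard deviation, rMSSD respects temporal
ordering, suppresses slow trends, and is less sensitive to
autocorrelation. For a stationary AR(1) process with marginal variance
$\sigma^2$ and lag-1 coefficient $\phi$,
$\delta \to \sqrt{2\sigma^2(1-\phi)}$; for white noise,
$\delta \to \sqrt{2}\sigma$. A configurable `denominator = "n-2"` variant
exists; the default follows the $n-1$ convention throughout.

**Whole-brain adjustment.** Network variabilities computed from raw signals
are dominated by a global component: in both real data and the synthetic
cohort, all network pairs correlate strongly across subjects, which makes
joint regression modeling unreliable. The adjustment computes each ROI's
successive-difference series $d_i(t) = x_i(t-1) - x_i(t)$, averages these
across ROIs into a global difference series $g(t)$, and residualizes each
$d_i$ on $g$ by OLS (with intercept) before applying the rMSSD form. By the
normal equations the residual difference series has exactly zero sample
covariance with $g$, so adjusted network variability is orthogonalized from
global signal variability — the analogue, on difference series, of global
signal regression. If $g$ is constant (degenerate regressor) the
differences are mean-centered instead. The adjustment operates at ROI
level, the analysis unit of the package; voxel-level input is out of scope.

Aggregation is the unweighted mean of $\delta_i$ over each network's member
ROIs; whole-brain variability is the mean over all ROIs, including
unassigned ones (so the whole-brain value is the ROI-count-weighted mean of
group means). Head motion is then residualized out of each network and
whole-brain summary column across subjects (OLS on mean framewise
displacement, with intercept). The motion step is applied to the summaries
rather than to each ROI because the summaries are what enter the
regressions; this is an explicit modeling assumption.

## 2. Measurement model (CFA)

The 14 task scores measure four correlated factors: cognitive flexibility
(CST, LF, CF, TMT-B, CS), inhibitory control (CWI-I, CWI-S), processing
speed (TMT-A, TMT-MS, RT), and working memory (0-back, 1-back, 2-back,
CPT). Timed scores (trail making, color-word interference, reaction times)
are negated first so every indicator points in the ability direction; the
orientation is guarded against double application.

The model is fit by maximum likelihood: minimize
$F_{ML} = \ln|\Sigma(\theta)| - \ln|S| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - p$
over $\Sigma = \Lambda\Phi\Lambda^\top + \Theta$, with unit-variance
factors and all loadings free — the identification under which the baseline
model has $14\cdot15/2 - (14 + 14 + 6) = 71$ degrees of freedom, and the
model with four freed residual covariances has 67. Fit statistics use the
standard conventions: $\chi^2 = (n-1)F_{ML}$ (configurable to $n$), RMSEA
$= \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$, CFI against the independence
baseline, SRMR as the root mean squared standardized residual over the
$p(p+1)/2$ unique covariance elements. Thresholds of poor fit are
CFI < 0.95, RMSEA > 0.08, SRMR > 0.06.

Numerical choices: residual variances are parameterized on the log scale
with a floor of $10^{-6}\,s_{jj}$ (solutions at the floor are flagged as
Heywood cases); the factor correlation matrix is parameterized by
normalized Cholesky rows, which is positive definite with unit diagonal for
any parameter value; gradients are analytic for loadings and residual
(co)variances and numeric for the six correlation parameters; optimization
runs quasi-Newton (`nlminb`) from two deterministic starts with an
L-BFGS-B polish, and factor signs are normalized so each factor's mean
loading is positive. Missing task scores are dropped listwise.

**Modification.** Residual covariances may be freed only between indicators
drawn from the same cognitive task and loading on the same factor (eight
eligible pairs: the three fluency pairs, TMT-A–TMT-MS, CWI-I–CWI-S, and the
three n-back pairs). Candidates are ranked by a univariate score-test
modification index, $(n-1)g^2/(2h)$, computed from the analytic gradient
and a numeric second derivative of $F_{ML}$ with respect to the candidate
covariance at the fitted solution; the full information-matrix version is
not implemented, but the univariate index is sufficient for ranking (a
planted residual covariance is recovered first in tests) and strictly
sharper than the standardized-residual fallback. The default workflow
(`fitEfModel`) frees the top four pairs — the count fixed by the df drop
71 to 67 — and refits; which four pairs are chosen is data-dependent.

**Factor scores** use the regression method,
$W = \Phi\Lambda^\top\Sigma^{-1}$, applied to centered indicators from the
modified model. The weights equal the population regression of factors on
indicators, which tests verify against an empirical simulation oracle.

## 3. Life-span regressions

Each factor score is regressed on one variability predictor at a time —
whole brain plus five networks, adjusted and motion-residualized — with
sex, handedness, and years of education as covariates; 4 outcomes by 6
predictors by {main, interaction} gives 48 models. Predictors enter one
per model because the unadjusted (and even adjusted) network summaries are
too collinear for joint inclusion. In interaction models age is
mean-centered and the product term `delta × age` is added; the interaction
coefficient is invariant to the centering constant (tested identity).
Standardized coefficients are $b\,\mathrm{sd}(x)/\mathrm{sd}(y)$; the
interaction beta comes from a refit with outcome, predictor, and age
z-scored before forming the product.

False-discovery-rate correction is Benjamini–Hochberg within each (outcome,
effect-type) family of six predictors — the family structure that produces
tied adjusted p-values across predictors within a row. The step-up rule is
delegated to `stats::p.adjust(method = "BH")` and checked against a
brute-force implementation of the step-up definition in tests.

Interactions surviving q < 0.05 are probed by simple slopes at the four
cohort mean ages (13.17, 27.01, 50.09, 69.42 years): the conditional slope
at centered age $a$ is $b_\delta + a\,b_{int}$ with delta-method variance
$\mathrm{Var}(b_\delta) + a^2\mathrm{Var}(b_{int}) +
2a\,\mathrm{Cov}(b_\delta, b_{int})$, t-tested on the residual df. The
delta-method results are exactly equal (to 10 decimal places in tests) to
refitting the model with age centered at the probe age, so either
convention gives identical inference. Age trajectories of each factor are
summarized by polynomial fits on orthogonalized age powers (default degree
2, with the peak age $-b_1/(2b_2)$ reported for concave fits).

## 4. Synthetic cohort

Because the motivating study's data are access-restricted, the package
ships a generator that emulates the study's structure with known ground
truth; every stage above is validated by recovery against it.

Defaults are the study conditions: 724 subjects, ages uniform on 6–85
(the real cohort's age histogram is not public; uniform is a neutral
choice and configurable), 57% female, 10% left-handed, education increasing
with age into adulthood, 423 timepoints at TR = 1.4 s, 246 ROIs split
CEN 40 / DMN 50 / SN 30 / LN 30 / DA 30 / unassigned 66.

Signals are sums of independent unit-variance AR(1) processes
(lag-1 coefficient 0.3): a shared global component $G(t)$ scaled by
`globalWeight` times a per-subject amplitude, plus an idiosyncratic process
per ROI scaled so the ROI's network-specific expected rMSSD equals its
network's target $d$: $s_i = d/\sqrt{2(1-\phi)}$. Network targets follow
age trends (CEN/DMN declining, SN rising, LN mildly rising, DA mildly
declining, with the unassigned slope balancing the ROI-weighted mean slope
to zero) plus between-subject deviations (SD 0.1) that are centered across
the brain by ROI count. Two structural choices matter:

* **Motion inflates the global amplitude, not network-specific
  variability.** Head motion produces brain-wide signal excursions, so the
  generator routes the motion effect (and a lognormal-scale subject
  amplitude, SD 0.4) through the shared component. Raw variability is
  therefore motion-confounded and globally dominated — all network pairs
  correlate above 0.7 — while the whole-brain difference adjustment removes
  it, reproducing the qualitative before/after contrast of the study.
* **Subject deviations are centered across the brain.** The subject's
  global level is carried by the amplitude; what remains is how
  variability is distributed across networks relative to that level, so
  the ROI-weighted mean deviation is exactly zero. A consequence is that
  adjusted whole-brain variability carries almost no between-subject
  signal, and correlates below 0.1 with every adjusted network
  variability — the orthogonality the adjustment is designed to produce.
  A side effect is that network deviations are slightly negatively
  coupled; the generator does not reproduce the strongly positive
  post-adjustment coupling of CEN/DMN/SN seen in real data.

Mean framewise displacement follows a U-shaped age curve
$0.20 + 10^{-4}(age - 40)^2$ plus noise (SD 0.06), floored at 0.03 mm —
mean about 0.25 mm, SD about 0.09, highest in childhood and old age.

Task scores derive from four correlated factors:
$f_k = \text{quadratic}(age_c) + \sum_{net}[\gamma_{main}\delta_{net} +
\gamma_{int}\,\delta_{net}\,age_c] + u_k$ with factor residual SD 0.8 and
residual correlation 0.6; indicators are $\lambda_j f + e_j$
($\lambda = 0.8$, noise SD 0.6 on the latent scale), relocated to
published-style means and SDs per task, and timed indicators are emitted
with reversed sign. The CPT descriptive scale (mean 480 ms, SD 120 ms) is
invented for symmetry with the other reaction-time scores. The default
quadratic age curve peaks at age 45; the default effects are a negative
limbic main effect ($\gamma = -1.5$ per delta-unit, about $-0.15$ SD per
delta-SD) on all four factors and age-moderated DMN (+0.08 per
delta-unit-year) and CEN (−0.08) effects, mirroring the qualitative
pattern the analysis is designed to detect.

By default the score pathway uses the generative delta targets, keeping
ground truth exact; an end-to-end mode feeds re-estimated variability
instead. For simulation studies that do not need time series,
`measuredVariabilityFromTruth()` adds the analytic estimation noise of the
rMSSD pipeline (relative SE $\approx \sqrt{1/(2(T-1)n_k)}$ for a group of
$n_k$ ROIs over $T$ timepoints, which matches the empirical noise of the
full pipeline at the default scan length) so that regression simulations
see the same measurement error structure at a fraction of the cost.

# What the simulations do and do not show

Problem sizes used by the test suite were chosen to make Monte-Carlo error
small relative to each tolerance: analytic rMSSD checks at $n = 10{,}000$
(i.i.d.) and $50{,}000$ (AR(1)); the adjustment contrast on a full-size
cohort of 500 subjects; CFA loading recovery at $n = 5{,}000$; null
calibration of the interaction t-test over 1,000 replicates at $n = 724$
(with a linear generative age curve, so the fitted mean structure is
correct under the null and the nominal level is the right benchmark);
planted-effect power over 200 replicates at the default effect sizes. In
the null-calibration loop the factor-score weights are estimated once from
an independent null cohort and held fixed, so each replicate's outcome is a
fixed linear functional of its indicators and the t-test's exactness is
preserved; power replicates refit the CFA each time (base model — the
generative model plants no residual covariances).

Two caveats on interpreting recovery results. First, when the generative
age curve is quadratic but the moderation model is linear in age, the
interaction estimate absorbs part of the curvature through the
delta-by-age product's correlation with age squared; the estimator is
unbiased when the fitted mean structure is correct (verified with the
curve zeroed), and under the defaults the planted signs remain correctly
detected. Second, the synthetic data are clean by construction — no
scanner artifacts, physiological noise, preprocessing residue, atlas
misassignment, or non-uniform age sampling — so passing recovery tests
demonstrates correctness of the estimators under the generative model, not
robustness of the scientific conclusions to real-data pathologies.

# Known limitations

* ROI-level only; no volumetric/NIfTI ingestion or preprocessing.
* Full-information ML for missing task scores is not implemented
  (listwise deletion); no RMSEA confidence intervals; no
  categorical-indicator estimators.
* Modification indices are univariate approximations (see above).
* The generator's residual structure after adjustment is compositional
  (see above); its inter-network correlations after adjustment are not
  calibrated to real data.
* No mixed-effects/longitudinal modeling, mediation, or vascular-confound
  adjustment.
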