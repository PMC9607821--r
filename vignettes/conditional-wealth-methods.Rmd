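---
title: "Conditional wealth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional wealth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condwealth)
```

## The problem

Birth cohorts and household panels in low- and middle-income countries
usually lack reliable income data, so socio-economic position is proxied by
an asset index: the first principal component of ordinal indicators of
durable-good ownership, housing quality and utility access. A
cross-sectional index is re-standardized at every wave, so it can rank
households within a wave but cannot express a change in mean wealth or in
asset-based inequality between waves. `condwealth` implements the
*temporally-harmonized* alternative — one set of item loadings estimated on
all household-waves pooled — together with a decomposition of each wave's
wealth into the part predicted by the household's own wealth history and a
*conditional wealth* residual, the package's measure of relative wealth
mobility over the preceding interval.

## The model

### Harmonized index

Let $x_{ik}$ be the ordinal code of item $k$ for household-wave row $i$.
Each item is assumed to discretize a latent normal variable at fixed
thresholds, so the association between two items is summarized by their
polychoric correlation: the correlation of the underlying bivariate normal
that best explains the observed cross-tabulation. We estimate it in two
steps — thresholds from the margins as inverse-normal quantiles of
cumulative proportions, then the correlation by maximizing the
bivariate-normal cell-probability likelihood with `optimise()`. The
bivariate normal CDF is evaluated through the identity
$\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \int_0^\rho \phi_2(h,k,r)\,dr$
with a 48-node Gauss–Legendre rule; the integrand is smooth for
$|\rho| \le 1-10^{-6}$, so this is accurate to near machine precision.

The index is the first eigenvector of the item-by-item polychoric matrix,
estimated on *pooled* household-wave rows. Scoring is the documented linear
rule: each item contributes its loading times its standardized code
(centered and scaled by the pooled code moments), and scores are
standardized so the pooled distribution has mean 0 and unit variance. The
scoring rule is isolated in `score_households()` so an alternative (e.g.
normal scores) could be swapped in; standardization is over the pooled
distribution, not per wave — without that, mean changes between waves would
be meaningless.

### Distributional change

For waves $t_1, t_2$ the package reports the change in mean wealth
$\mathrm{E}[W_{t_2}]-\mathrm{E}[W_{t_1}]$, per-household wealth changes
$w_{i,t_2}-w_{i,t_1}$, the change in the inequality share
$\sqrt{\mathrm{Var}[W_{t_2}]/\sum_T \mathrm{Var}[W_T]}$ (the partition of
total across-wave variance), and per-household rank changes. Because the
cohort is closed, rank changes sum to zero exactly (ties get average
ranks), and the squared inequality shares sum to one.

### Conditional wealth

For each wave $t \ge 2$, ordinary least squares of $w_t$ on
$(w_1,\dots,w_{t-1})$ gives

$$ w_{i,t} = b_0 + b_1 w_{i,1} + \cdots + b_{t-1} w_{i,t-1} + c_{i,t}, $$

and the residual $c_{i,t}$ is conditional wealth: mean zero, uncorrelated
with every earlier wave, and kept in harmonized-index units so a unit is
comparable across waves. The share
$\mathrm{Var}[c_t]/\mathrm{Var}[w_t]$ measures how much of the wave's
dispersion is positional mobility rather than persistence. If successive
waves are canalized (rank correlation near one) this share collapses and
the interval is a poor choice; `canalization_diagnostics()` flags such
intervals, and exactly collinear histories abort the fit (condition number
$> 10^8$) rather than being silently pseudo-inverted.

Two stage-1 variants are provided. The default regresses on wealth history
only, matching the conditional-growth convention; `fit_conditional_adjusted()`
additionally enters declared covariates, making the residual orthogonal to
them as well. The default is the package's primary parameterization because
the predictor models (below) are then interpretable as the absorbed effect
of covariates on mobility.

### Outcome and predictor models

Outcome models obey one adjustment rule, enforced by
`build_adjustment_set()`: adjust for the anchor (first) wealth measure, all
conditional measures up to the target wave, and life-course covariates —
never for a later raw wealth measure, which is an exact linear combination
of the anchor and the conditionals. The conditional parameterization

$$ \mathrm{E}[y] = a_0 + a_1 W_1 + \textstyle\sum_{t\ge2} a_t C_t +
   \text{covariates} $$

spans the same column space as the regression on raw measures
$(W_1,\dots,W_T)$, so the two fits have identical fitted values, identical
coefficients on the latest measure, and an anchor coefficient related by
$a'_1 = \sum_t a_t \pi_t$ with $\pi_1 = 1$,
$\pi_t = \sum_{s<t} b_{t,s}\pi_s$ (for two waves,
$a'_1 = a_1 + a_2 b_1$). `check_equivalence()` verifies all three
identities numerically; they are exact properties of least squares, not
statistical approximations.

Predictors of mobility are modeled by `predict_conditional()`: OLS of
$c_t$ on covariates, excluding the anchor by construction (conditional
wealth is uncorrelated with it, and adjusting for it is refused with an
error). `stratified_fit()` repeats the outcome model within groups (e.g.
sex) using the pooled conditional measures; no interaction tests are run.

Standard errors are classical OLS by default, with HC1 behind
`robust = TRUE`. Because conditional measures are themselves estimated, the
naive second-stage SEs ignore first-stage noise; a household-resampling
bootstrap (`bootstrap = n`) that re-estimates the decomposition inside
every replicate is the honest alternative and is labeled as such in the
output.

## The synthetic cohort generator

`simulate_cohort()` draws a closed cohort with known ground truth: latent
wealth $w_{i,1} \sim N(\mu_0, \sigma_0^2)$ and
$w_{i,t} = \alpha_t + \beta_t w_{i,t-1} + \text{shifts} + e_{i,t}$,
$e_{i,t} \sim N(0, \tau_t^2)$; ordinal items that discretize
$\lambda_k w_{i,t} + N(0,1)$ at fixed thresholds (the unit measurement
noise matches the bivariate-normality assumption behind polychoric
correlation, so loadings are interpreted on that scale); covariates with
treatment-confounder feedback (maternal schooling shifts initial wealth and
the first innovation; per-wave rural residence shifts innovations; attained
schooling is $\gamma w_1$ plus noise, so it is both a consequence of early
wealth and a predictor of later mobility); and an outcome
$Y_i = a_0 + a_1 w_{i,1} + \sum_t a_t e_{i,t} + \text{covariates} +
N(0,\sigma_y^2)$ built from the *true* innovations, never from fitted
residuals, so recovery studies measure estimation error honestly. One
global seed is split into fixed per-component streams, so adding items
cannot reshuffle covariates.

### The CLHNS-like default conditions

`clhns_like_config()` fixes the study conditions: 1581 households, seven
waves labeled 1983–2009, 30 items (18 binary, 8 three-level, 4 four-level).
The AR parameters are derived in closed form from the published wave means
$m_t$, SDs $s_t$ and unexplained shares $u_t$ of the cohort the framework
was illustrated on: $\tau_t = s_t\sqrt{u_t}$,
$\beta_t = s_t\sqrt{1-u_t}/s_{t-1}$, $\alpha_t = m_t - \beta_t m_{t-1}$.
Effect sizes default to the published magnitudes: 0.04 index units per year
of maternal schooling on the first-interval innovation, −0.2 for rural
residence, and outcome coefficients 0.40 (anchor), 0.36 (first
conditional), 0.43 (last conditional) on a BMI scale with noise SD 4
(chosen so coefficient SEs at $n \approx 1580$ match the published CI
widths). Item cut points sit on the latent scale and span ±1.9 latent
units so the battery discriminates among the poorest households of the
earliest wave; loadings 1.2–2.6 give index reliability ≈ 0.97. With these
choices the simulated pipeline reproduces the published wave summary table
closely (e.g. unexplained share ≈ 0.55 vs 0.51 in the first interval).
What remains unmatched is deliberate: binary items still compress the
earliest wave's SD slightly (truncation — an intrinsic asset-index
pathology), the real item list and level counts are not public, and no
attrition or household re-composition is simulated (only an optional MCAR
mask). Passing tests on this generator therefore demonstrate correctness
of the estimators under the stated measurement model, not robustness to
informative missingness or migration.

### The parameter-recovery scenario

`recovery_config()` is the scenario used for bias/coverage studies:
same wealth dynamics, outcome coefficients at the published magnitudes,
but (i) no covariate effects on innovations, so the unadjusted stage-1
residual coincides with the true innovation in population and the study
isolates pure estimation error, and (ii) outcome noise SD 2, so that with
200 replicates of $n = 1500$ the Monte-Carlo SE of the mean coefficient is
about 0.006 — small enough to resolve biases well below the 0.02 level the
recovery suite checks. These sizes (200 × 1500) also keep the default test
run fast on a single CPU.

## Numerical choices

* Variances use the unbiased ($n-1$) denominator everywhere; every variance
  identity asserted in tests is exact under a consistent denominator, and
  the unexplained share is denominator-free.
* Thresholds and polychoric likelihoods apply a 0.5 continuity correction
  to empty cells/levels, flagged in the result.
* Polychoric estimates within $10^{-4}$ of $\pm1$ are clamped to
  $\pm(1-10^{-6})$ and flagged as boundary cases.
* A polychoric matrix with eigenvalues below $-10^{-8}$ (possible under
  pairwise-complete estimation) is repaired by eigenvalue clipping and
  re-scaling to unit diagonal, and flagged.
* The eigenvector sign is fixed by correlating raw scores with the pooled
  sum of standardized codes; rank ties always get average ranks.
* Confidence intervals are Wald intervals, estimate ± 1.96 SE.
* Pipeline artifacts are stamped with an FNV-1a fingerprint of the
  configuration plus the seed; identical config and seed reproduce
  identical artifacts (the run log additionally records stage timings, so
  it is excluded from byte-level comparisons).

## Worked example

```{r example}
cfg <- clhns_like_config(n_households = 300, seed = 1)
res <- run_pipeline(pipeline_config(cfg, seed = 1))
res$mobility
res$conditional
res$equivalence$pass
```

## Known limitations

* Only linear stage-1 models: nonlinear conditional measures lose the
  interpretation as residuals orthogonal to the full history.
* The anchor-first decomposition is the only one implemented; anchoring on
  the last measurement answers a different question and is left out.
* No correction for migration or household splits/merges, and no
  g-methods for treatment-confounder feedback; estimates are associational.
* Naive two-stage SEs understate uncertainty; use the bootstrap option
  when the conditional measures are noisy.
* Indices built from rare items are unstable; the prevalence filter
  (default minority share 0.01) should be kept on.
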