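# condwealth

Conditional wealth and asset-based mobility for longitudinal cohorts.

## What problem this solves

Cohort studies in low- and middle-income countries rarely have usable income
data; household wealth is proxied by an **asset index** — the first principal
component of ordinal indicators of durable-good ownership, housing quality
and utility access. Indices built separately per study wave are
re-standardized each time, so they can rank households *within* a wave but
cannot express changes in mean wealth or asset-based inequality *between*
waves, nor the magnitude of a household's movement through the wealth
distribution.

`condwealth` is for epidemiologists and social scientists analyzing closed
cohort panels of ordinal asset items. It provides:

1. a **temporally-harmonized asset index**: polychoric correlations among
   items pooled over all household-waves, first principal component, one
   scoring rule for every wave (`build_harmonized_index()`,
   `score_households()`);
2. **distributional-change metrics**: change in mean wealth, per-household
   wealth change, change in each wave's share of total across-wave variance,
   and rank changes (`mobility_summary()` and friends);
3. **conditional wealth**: for each wave `t`, the residual of

   ```
   w_t = b0 + b1 w_1 + ... + b_{t-1} w_{t-1} + c_t
   ```

   — the component of current wealth unexplained by the household's wealth
   history, in index units, with `Var(c_t)/Var(w_t)` quantifying positional
   mobility over the interval (`fit_conditional()`, `unexplained_share()`,
   `canalization_diagnostics()`);
4. **association models** under the adjustment rule appropriate for
   conditional measures — anchor wealth, conditional measures and
   covariates, never a later raw wealth measure — plus predictor-of-mobility
   models and verification of the exact equivalence between the conditional
   and raw-measures parameterizations (`fit_outcome_conditional()`,
   `fit_outcome_fixed()`, `check_equivalence()`, `predict_conditional()`,
   `stratified_fit()`);
5. a **synthetic cohort generator** with known latent autoregressive wealth,
   ordinal measurement, covariate feedback and outcome model, for
   parameter-recovery studies (`simulate_cohort()`, `clhns_like_config()`);
6. an **end-to-end pipeline** with CSV/JSON input and output and a thin
   command-line wrapper (`run_pipeline()`, `inst/cli/condwealth.R`).

## Worked example

Simulate a 300-household, 7-wave cohort emulating a Philippine birth cohort
and run the whole pipeline:

```r
library(condwealth)
cfg <- clhns_like_config(n_households = 300, seed = 1)
res <- run_pipeline(pipeline_config(cfg, seed = 1))
res$mobility
#> Wave-level wealth summary (n = 300 households)
#>  wave    mean    sd inequality_share mean_change inequality_change
#>  1983 -0.9857 0.670            0.286          NA                NA
#>  1991 -0.2573 0.979            0.418      0.7284           0.13187
#>  1994 -0.0383 0.936            0.399      0.2191          -0.01846
#>  1998  0.1557 0.933            0.398      0.1939          -0.00117
#>  2002  0.2130 0.850            0.363      0.0573          -0.03514
#>  2005  0.4175 0.912            0.389      0.2045           0.02613
#>  2009  0.4952 0.883            0.377      0.0777          -0.01213
```

Mean wealth rises by 0.73 index units over the first interval while the
1991 wave's inequality share jumps by 0.13: the cohort got richer on
average *and* more unequal. The conditional decomposition shows how much of
each wave's dispersion is positional mobility rather than persistence:

```r
res$conditional
#> conditional_wealth_model (wealth-history only): 300 households, waves 1983, ...
#>  wave sd_conditional unexplained_share
#>  1991          0.689             0.496
#>  1994          0.460             0.242
#>  1998          0.520             0.311
#>  2002          0.507             0.355
#>  2005          0.558             0.375
#>  2009          0.521             0.348
```

Half the 1991 variance (0.496) is unexplained by 1983 wealth — substantial
re-ranking over the first eight years — while later intervals are more
persistent. The outcome model then reads each conditional coefficient as
the change in outcome (here BMI-like, kg/m²) per index-unit of relative
wealth mobility in that interval:

```r
subset(res$fit_conditional$coefficients,
       term %in% c("w_1983", "c_1991", "c_2009"))
#>     term estimate    se   lower upper
#> 2 w_1983  -0.0515 0.350 -0.7380 0.635
#> 3 c_1991   0.6192 0.337 -0.0421 1.281
#> 8 c_2009   0.4031 0.436 -0.4521 1.258
res$equivalence$pass
#> [1] TRUE
```

(At n = 300 the single-cohort coefficient SEs are ~0.35, so point estimates
scatter widely around the generating values 0.40 / 0.36 / 0.43; the
acceptance script below averages 200 replicates at n = 1500 to pin them
down.) `res$equivalence$pass` confirms the fixed-effects and conditional
parameterizations agree exactly on the shared identities.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites; `vignettes/conditional-wealth-methods.Rmd` — model, assumptions,
  generator calibration and design notes; `inst/cli/condwealth.R` — command
  line (`simulate`, `build-index`, `mobility`, `conditional`, `associate`,
  `run`); `inst/extdata/` — a tiny CSV fixture.
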