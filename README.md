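# flymort

Age-specific mortality analysis for laboratory *Drosophila* cohorts
reared as replicated inbred isolines under crossed sex and
developmental-treatment designs — the kind of assay used to ask whether
a developmental manipulation (here: larval rapamycin exposure, which
yields small-celled adults) changes adult mortality, and at which ages.

The package is written for quantitative biologists and biodemographers
who have one row per fly — isoline, sex, treatment, age at death or
censoring on a transfer-check grid — and want the full analysis chain:

* **Kaplan–Meier survivorship** per group and **stratified
  Gehan–Breslow permutation tests** (generalized Wilcoxon, early-death
  weighted; exact, Monte-Carlo or asymptotic null), robust to
  non-proportional hazards and crossing curves.
* **Penalized-spline Poisson hazard models**: life-table death counts
  `D` with log fly-day exposure `log E` as offset,

  `log mu(x) = eta_{sex,trt} + f_{sex,trt}(x) + g_isoline(x)`,

  with cubic P-spline age smooths per sex x treatment group, isoline
  random intercepts or factor-smooth deviations, AIC-selected smoothing
  and AIC model selection (`hazgam()` returns a classed fit with
  `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
  `simulate`, `logLik`/`AIC` methods).
* **Marginal vs conditional mortality**: population-level hazards
  `mu_bar(x) = sum_i w_i(x) mu_i(x)` with survivorship weights
  `w_i(x) ∝ S_i(x)`, capturing the survivor-composition effects of
  heterogeneity in frailty among isolines, versus baseline predictions
  with line effects removed from the prediction only.
* **Bootstrap percentile difference bands**: pointwise 95% intervals
  for log-mortality differences between groups from design-preserving
  individual resampling, plus maximal significant age-window calling.
* A **synthetic-cohort generator** (`simulate_cohort()`) with Gompertz
  baseline `log mu = log a + b x`, log-normal isoline frailty, an
  early-adult treatment mortality hump, 3-day transfer discretization
  and escape censoring — so the whole pipeline is testable against
  exact theory (`true_marginal_hazard()` is the closed quadrature
  oracle for the frailty mixture).

## Worked example

```r
library(flymort)

design  <- cohort_design(n_isolines = 6, n_per_group = 60, max_age = 250)
params  <- gompertz_frailty_params()        # Gompertz + frailty + hump
records <- simulate_cohort(design, params, seed = 2024)
lt      <- build_lifetable(records)

km_fit(records)
#> Kaplan-Meier curves for 4 group(s)
#>   female.control               events  355   median 30 days
#>   female.rapamycin             events  357   median 27 days
#>   male.control                 events  349   median 27 days
#>   male.rapamycin               events  357   median 27 days

gehan_breslow_test(records, compare = "treatment", strata = "sex", seed = 1)
#> Stratified Gehan-Breslow test on 'treatment' (monte_carlo)
#>   score sum (control) = 19599, z = 2.518, p = 0.0122
#>   strata: female, male

sel <- select_hazgam(lt, list(
  shared   = hazgam_spec(smooth = "shared",   isoline = "intercept"),
  by_group = hazgam_spec(smooth = "by_group", isoline = "intercept")))
sel
#> AIC model selection, 2 candidates
#>      model    aic delta_aic     edf
#> 1 by_group 1525.4     0.000 13.9886
#> 2   shared 1527.1     1.683  9.4063

summary(sel$best)
#> Penalized-spline Poisson hazard model
#>   smooth: by_group | isoline: intercept | fixed: sex + treatment + sex:treatment
#>   n bins 402, deaths 1418, exposure 38547 fly-days
#>   EDF 13.99, logLik -748.73, AIC 1525.44
#>   deviance 344.86, crude hazard 0.03679/day
#>   central-range conditional log-hazard slope (per day):
#>   female.control female.rapamycin     male.control   male.rapamycin
#>           0.0720           0.0631           0.0721           0.0588

boot <- bootstrap_refits(records, sel$best, n_boot = 300, seed = 1)
difference_band(boot, "female.control", "female.rapamycin",
                flavor = "marginal")
#> marginal log-mortality difference: female.control - female.rapamycin (alpha = 0.05)
#>   negative window: 1.5-16.5 days
```

Reading the output: the AIC winner keeps separate age smooths per
sex x treatment group (the treated groups have a different early age
pattern); the fitted conditional log-hazard slopes near 0.06–0.07/day
estimate the Gompertz ageing rate; and the difference band flags ages
1.5–16.5 days where rapamycin-treated females have significantly
*higher* log mortality than controls (a negative control-minus-treated
difference), i.e. an early-adult mortality hump that later vanishes.

`run_pipeline(pipeline_config(records, ...))` executes the whole chain
(life table, KM, both stratified tests, model selection, all four
difference bands) and writes CSV/JSON artifacts plus a manifest with
input/output checksums and a reproducible content hash.

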