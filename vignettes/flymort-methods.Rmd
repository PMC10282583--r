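---
title: "Age-specific mortality of isoline fly cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-specific mortality of isoline fly cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A standard laboratory assay for intrinsic mortality in *Drosophila*
follows cohorts of adult flies until death: inbred isolines (the unit of
genetic replication), both sexes, and a developmental treatment — here
larval rapamycin exposure, which yields small-celled adults — crossed in
a factorial design.  Flies live in vials, are transferred to fresh food
every three days, and at each transfer dead flies are counted while
escaped or accidentally killed flies are recorded as right-censored.
Pooling vials gives roughly 90 flies per isoline x sex x treatment cell
across 14 isolines.

`flymort` implements the complete demographic analysis for such data:

1. **Nonparametric description** — Kaplan–Meier survivorship per group
   and stratified Gehan–Breslow (generalized Wilcoxon) permutation tests,
   which weight early deaths by the number at risk and therefore remain
   informative when hazards are non-proportional and survivorship curves
   cross.
2. **Age-specific mortality modelling** — a penalized-spline Poisson
   model of the binned death counts with log fly-day exposure as offset
   (the classic life-table likelihood), sex and treatment fixed effects,
   age smooths per sex x treatment group, and isoline random effects.
3. **Marginal vs conditional mortality** — population-level hazards that
   include the survivor-composition effect of heterogeneity in frailty
   among isolines, versus "baseline" predictions with line effects
   removed from the prediction but not from the model.
4. **Inference on differences** — pointwise bootstrap percentile bands
   for log-mortality differences between groups, and maximal age windows
   where the interval excludes zero.

Because the original records are not bundled, the package ships a
synthetic-cohort generator whose output has the same statistical
structure as the assay, so every stage is testable against known ground
truth.

## The hazard model

Records are reduced to a life table: per (isoline $i$, sex $s$,
treatment $t$, age bin $r$), a death count $D_r$ and an exposure $E_r$
in fly-days actually lived in the bin.  The binned mortality model is

$$D_r \sim \mathrm{Poisson}\{E_r\,\mu(x_r)\},\qquad
\log \mu(x) = \eta_{s,t} + f_{s,t}(x) + g_i(x),$$

where $x_r$ is the bin midpoint, $\eta_{s,t}$ collects the intercept,
sex, treatment and interaction fixed effects, $f_{s,t}$ is a
group-specific age smooth, and $g_i$ is the isoline term — either a
random intercept (a line-level proportional frailty on the hazard
scale) or a factor smooth: a full per-line smooth deviation, all lines
sharing one smoothing parameter, constrained to sum to zero across
lines at every age.

Smooths are P-splines: cubic B-splines on equally spaced knots
($k = 10$ basis functions per smooth by default) with a second-order
difference penalty.  The penalty null space spans constants and linear
trends, so a Gompertz log-linear trend $\log\mu = \log a + bx$ is never
penalized away; as $\lambda \to \infty$ each smooth collapses onto the
Poisson-GLM Gompertz line.  Each smooth block is column-centered over
its active rows so group intercepts stay identified; the factor-smooth
penalty adds a projection onto its null space, making the per-line
deviation penalty positive definite so that a single $\lambda$ shrinks
whole line deviations to zero (the mixed-model reading of a random
smooth).

Coefficients maximize the penalized Poisson log-likelihood by
Newton/penalized-IRLS iteration (gradient tolerance `1e-8` scaled by
total deaths, step halving for stability).  Smoothing parameters
minimize the conditional AIC, $-2\ell + 2\,\mathrm{EDF}$ with EDF the
trace of the influence matrix, over a log-spaced grid (`10^{-2}` to
`10^6`) with two local refinement rounds; group smooths share one
$\lambda$ and the isoline block has its own.  An optional
coordinate-refinement stage (`hazgam_control(untie = TRUE)`) gives every
penalty block its own $\lambda$, as mgcv does; the tied default proved
better calibrated for difference-band inference, so untying is opt-in.
REML selection is a known alternative and is not implemented; AIC keeps
one criterion for both smoothing and model selection.

Model selection over candidate structures (shared vs group-specific
smooths, with or without line terms) also uses AIC; ties break toward
fewer effective degrees of freedom.  Downstream inference uses the most
parsimonious model, which matters for calibration (below).

## Marginal and conditional curves

The conditional ("baseline") curve for a group sets $g_i \equiv 0$.
The marginal curve reweights the per-line predictions by each line's
surviving fraction,

$$\bar\mu(x) = \sum_i w_i(x)\,\mu_i(x),\qquad
w_i(x) = \frac{S_i(x)}{\sum_j S_j(x)},\qquad
S_i(x) = e^{-\int_0^x \mu_i(u)\,du},$$

with the cumulative hazard accumulated by the trapezoid rule on the age
grid and uniform weights at the grid start (equal initial line sizes).
Frail lines die out first, so $\bar\mu$ rises more slowly than any
line's own hazard — the classic deceleration signature of heterogeneity
in frailty.  The generator side has an exact counterpart,
`true_marginal_hazard()`, which integrates over the continuous
log-normal frailty distribution by Gauss–Hermite quadrature (nodes
doubled until the log-scale change is below `1e-8`); a variance-matched
gamma mixture with closed-form Laplace transform is available as a
cross-check.

## Bootstrap difference bands

Differences $\Delta(x) = \log\mu_A(x) - \log\mu_B(x)$ between two
sex x treatment strata (same flavor only; marginal and conditional are
never mixed) get pointwise percentile bands: individuals are resampled
with replacement within each isoline x sex x treatment cell (preserving
the design and line sizes), the life table is rebuilt, and the model is
refit with $\lambda$ and the design's centering constraints frozen at
the original fit.  At each grid age the band is the $\alpha/2$ and
$1-\alpha/2$ empirical quantiles of the replicate differences;
significant windows are maximal runs of grid ages whose interval
excludes zero, signed.  The grid is the life-table bin midpoints
restricted to ages observable (positive exposure) in both strata.

Implementation note: a resampled cohort's life table is a linear map of
the per-fly multiplicity vector, so replicates reuse the original
design matrix and only repeat the Poisson working fit — about 4 ms per
replicate at study scale.

Three deliberate choices, all flagged in the interface:

* **Resampling unit** — individuals within design cells, not whole
  isolines: with 14 lines a cluster bootstrap is too unstable.  Line
  effects are still re-estimated per replicate, so line-level
  uncertainty propagates through the refit.
* **$\lambda$ frozen** during resampling keeps replicates comparable and
  cheap; smoothing-selection variability is therefore not in the bands.
* **Pointwise bands** at 95%, no familywise correction.  Across ~40
  grid ages a fully flexible model would leak spurious windows at well
  above 5%; computing bands from the AIC-selected model contains this,
  because under group homogeneity the parsimonious (shared-smooth)
  model makes $\Delta(x)$ nearly flat and the effective number of
  independent ages collapses.  In null simulations at study scale the
  any-window rate is then near the nominal single-test level (~7%,
  versus ~35% when bands are always computed from the full interaction
  model).

## The synthetic-cohort generator

Each fly's hazard is
$$\mu_{i,s,t}(x) = \exp\{\log a_{s,t} + b\,x + z_i +
h\,\mathbf{1}[t=\mathrm{rapamycin}]\,e^{-x/d}\},$$
with one log-frailty $z_i \sim N(0, \sigma^2)$ per isoline shared by
all its flies.  Latent death ages invert the cumulative hazard at
Exp(1) deviates; deaths are then discretized **up** to the next 3-day
transfer (deaths are discovered at transfers); independent escape
censoring acts at each earlier check; flies outliving the horizon are
censored at the last check.  The generator rejects designs whose
horizon truncates more than half of the latent deaths.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| isolines x flies/cell | 14 x 90 | the assay's design scale |
| check interval | 3 d | transfer schedule |
| censoring/check | 0.002 | escape rate is not reported anywhere; a small placeholder, exposed in the design object |
| $b$ | 0.08 /d | Gompertz ageing slope of the same order as fly cohort estimates |
| $\sigma$ | 0.3 | visible inter-line spread (hazard ratio ~2 between extreme lines) |
| $h$, $d$ | 0.7, 10 d | early-adult excess of the treated group: doubled hazard at eclosion fading within ~3 weeks |
| $\log a$ | -5.3 (f), -5.0 (m) | see below |

The baseline deserves a note.  With $b$ fixed, $\log a$ controls both
the lifespan scale and the density of early-adult deaths.  We set it so
that the design retains the early-adult information the real assay
demonstrably had (its rank tests and difference bands resolve
early-life treatment effects): about 0.5–0.7% baseline daily mortality
at eclosion, which is high for outbred stocks but plausible for highly
inbred sib-mated isolines, and which the detectability analysis of the
early hump requires at this $b$.  The cost is a compressed lifespan
scale (medians near 30 days rather than the 60+ of long-lived stocks);
at a fixed Gompertz slope one cannot match both the lifespan scale and
the early-death density, and the package prioritizes the information
structure.  Males get a 0.3 log-unit excess, matching their generally
higher mortality.

What the generator does **not** emulate: vial-level effects (the assay
pools vials), within-line individual frailty, age-dependent escape
rates, late-life hazard plateaus beyond what log-normal frailty
induces, and any non-multiplicative action of the treatment.  Passing
tests therefore certify the pipeline's statistical behaviour under the
declared data-generating process, not the biology of any particular
stock.

## Interval censoring and the exposure convention

Observed ages sit on the 3-day transfer grid, and a fly discovered dead
at a transfer actually died up to 3 days earlier.  With the default
`"full"` endpoint convention (a death contributes its entire residual
to the endpoint bin) exposure is conserved exactly —
$\sum E$ equals the sum of observed ages — which is the natural
bookkeeping for life tables.  But once the hazard reaches the order of
the check interval ($\mu\Delta \gtrsim 0.3$), this convention
overstates the days lived by dying flies and biases the binned rate
$D/E$ low; at the oldest ages of a Gompertz cohort the bias reaches
tenths on the log scale.  The `"half"` convention (deaths contribute
half their residual — the actuarial correction) removes most of it.
Consequently fits meant to be compared against continuous-time theory
(slope recovery, marginal-vs-oracle checks) use `"half"`, while the
default pipeline keeps `"full"`.  The Gompertz slope estimator also
weights its least-squares fit by stratum exposure, so the sparse oldest
bins — where the residual bias concentrates — do not leverage the
slope.

## Problem sizes used by the test suite and acceptance script

All simulation-based checks state their sizes explicitly and were
chosen as the package's own trade-off between statistical resolution
and runtime: slope recovery uses 12 replicates at design scale
(14 x 90 x 4); hump-window power uses 15 replicates (300 bootstrap
refits each) and the null window rate 40 replicates; rank-test
calibration uses 500 null simulations of 40 flies with 999
permutations; the frailty-oracle comparison uses one cohort of 20 000
flies as 2500 lines x 2 flies/cell with daily checks, which makes the
realized frailty distribution dense enough that the continuous-mixture
oracle is approachable (with 14–100 lines, realized-frailty sampling
error alone exceeds the 0.1 log tolerance).  The acceptance script
(`scripts/acceptance.R`) recomputes single-cohort versions of the same
quantities from scratch under a caller-supplied seed.

## Known limitations

* AIC-based $\lambda$ selection undersmooths relative to REML in small
  strata; the conditional-AIC flavor (EDF-based) is used for both
  smoothing and structure selection.
* Bands are pointwise; a window should be read as an age range of
  pointwise significance, not a familywise-corrected discovery.
* The Poisson likelihood assumes no overdispersion beyond the modelled
  random effects; quasi-likelihood or negative-binomial extensions are
  out of scope.
* Binned hazards are biased at ages where $\mu\Delta$ is large even
  under the half-interval convention; conclusions about the very oldest
  ages should lean on the survivorship scale instead.
* No extrapolation: predictions outside the fitted age range error out
  by design.
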