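---
title: "Quantifying biparental care and evaluating sampling-window designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biparental care and evaluating sampling-window designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Studies of biparental care in cavity-nesting birds (zebra finches are the
canonical captive model) code nest-box video into behavioural event logs:
per-parent intervals of *care* (incubation before hatching, brooding after)
and of merely being *inside* the box, plus feeding bouts as point events.
From such logs one wants (i) accurate time-budget metrics per parent and per
pair, (ii) to know how consistent individuals are within and across days
(repeatability), and (iii) to know whether a short observation window placed
somewhere in the day is a trustworthy stand-in for a full-day recording —
the sampling-design question that decides how many hours of video a study
must code. `nestbudget` implements this whole chain, plus a generative
simulator of two-parent behaviour so every estimator can be exercised
against data whose truth is known.

## Effort metrics and interval algebra

All metrics are defined set-theoretically on half-open intervals
$[s, e)$ in seconds since local midnight:

* individual care = the parent's care track; individual *nest attendance* =
  care $\cup$ inside;
* *joint* effort = male set $\cap$ female set (both parents
  simultaneously); *total* effort = male set $\cup$ female set (at least
  one parent);
* the *proportion of male feedings* = $m/(m+f)$, a count ratio over feeding
  bouts in the window (undefined — `NA` — when no parent fed).

Effort in a window $[a, b)$ is occupied time divided by *observable* time,
where observable excludes footage gaps. These operations are computed
exactly (merge/sweep algorithms on sorted endpoint matrices), and the test
suite checks them against an independent 1-second rasterization oracle on
thousands of random cases, together with the inclusion–exclusion identity
$\text{male} + \text{female} - \text{joint} = \text{total}$, which holds
exactly, not approximately.

Half-open windows mean a boundary instant belongs to the later window, so a
day partitions cleanly. A window whose observable time falls below 95% of
its nominal width (configurable `min_observable`) is treated as missing:
this reproduces the reduced ANOVA denominators (e.g. df $9,107$ instead of
$9,110$) that a ~1.5 h mid-recording footage loss produces in a 10-nest,
12-window design.

## Repeatability (Harper's one-way ANOVA method)

Rows of an effort matrix (nests, or parents nested in nests) are groups;
windows within a day — or days within a stage — are repeated measures. From
the one-way ANOVA with among- and within-group mean squares $MS_A, MS_W$
and effective group size
$n_0 = \left(N - \sum_i n_i^2/N\right)/(k-1)$,
the among-group variance component is $s_A^2 = (MS_A - MS_W)/n_0$ and the
intraclass repeatability is

$$ r = \frac{s_A^2}{s_A^2 + MS_W}, $$

which for a balanced design reduces algebraically to
$r = (F-1)/(F+n-1)$; the suite verifies the identity to $10^{-12}$.
Design choices:

* **Negative estimates are reported, not truncated.** Truncation at 0 would
  bias averages of estimates upward; the `negative` flag marks them.
* **Gating.** Following the convention of the field's published tables,
  `repeatability_table()` always computes $r$ but blanks the *displayed*
  value when the ANOVA is not significant at `alpha` (default 0.05).
* **Printed-table comparisons round to 2 decimals first.** Published means
  and paired $t$ statistics for 1 h vs 3 h windows derive from 2-dp table
  values; `window_width_comparison()` reproduces that pipeline, and the
  acceptance suite recovers the published $t = -11.93, -7.93, -9.92, -4.49$
  exactly at 2 dp.
* **Unbalanced designs** use Harper's $n_0$. For a published table computed
  from an unbalanced design only the balanced shortcut from the printed
  $F$ is recoverable; `harper_r_from_f()` provides exactly that
  reconstruction, and for the reference day-13 design ($n_0 \approx 11.7$)
  the two differ only in the third decimal.

## Window-versus-daily prediction

For each metric and each 1 h or 3 h window, `prediction_table()` regresses
per-nest daily effort on per-nest window effort (simple OLS; $R^2 = 1 -
SS_{res}/SS_{tot}$, slope $t$-test) and attaches a nonparametric bootstrap
CI: nests — the independent unit — are resampled with replacement, $10^4$
replicates by default, percentile 2.5/97.5 bounds. The percentile interval
was chosen because the published analysis names only "nonparametric
bootstrapping" and the percentile interval is transformation-respecting and
has no tuning constants; resamples with zero predictor variance (possible
with few nests or tied values) are discarded and redrawn, counted, and
warned about when they exceed 1% of draws. Seeds are explicit everywhere;
identical seeds give identical CIs. A useful exact identity used as a test:
with no gaps a 3 h window value is the mean of its three 1 h values, so the
3 h $R^2$ is reproduced exactly by regressing on averaged 1 h values.

## Mixed models

Diurnal trends: `fit_diurnal()` fits, by maximum likelihood, effort on an
orthogonal polynomial of window index (degrees 1–6) with a random intercept
per nest, selects the degree by AIC (ties toward the lower degree,
threshold $10^{-6}$), and tests the selected model against the
intercept-only null by a likelihood-ratio test. ML rather than REML is used
throughout because the compared models differ in fixed effects — the
statistically required choice where the source analysis is silent. Degree 0
is included as the LRT null even though the selection range starts at 1.
Because the selected degree is chosen to minimize AIC, the null
distribution of the LRT p is mildly anti-conservative; the type-I test in
the suite therefore bounds the false-positive rate rather than asserting
exact uniformity.

Division of labour: `fit_division()` models per-parent effort with sex,
stage (factor over stage days) and their interaction as fixed effects and
parent nested in nest as random intercepts, all terms tested by LRTs
between ML fits (df 1 for sex, $k-1$ for stage, $k-1$ for the
interaction). Singular random-effect fits are tolerated (lme4 boundary
fits), matching how such models behave on small behavioural data sets; at
$\theta = 0$ the ML deviance provably equals the OLS deviance, which the
suite checks via `devFunOnly`.

## The behavioural simulator

`simulate_nest()` runs each parent as a three-state jump process
(`off` / `inside` / `care`) in continuous time with piecewise-constant
hazards on a 1-minute grid — exact simulation by competing exponential
clocks re-drawn at events and grid boundaries, not a discrete-time
approximation. Log-hazards of care entry receive a diurnal polynomial in
scaled time of day, an additive per-(stage, day) shift, and a per-parent
Gaussian intercept (the same shift and intercept are subtracted from care
exits, so each knob moves care occupancy monotonically); while the partner
is in care both care-entry hazards are multiplied by `joint_coupling`.
Feeding bouts are a Poisson process while the parent is in the nest,
provisioning stage only.

What the defaults state: `preset_paperlike()` was calibrated once, before
the acceptance thresholds were evaluated as tests, to the qualitative
structure reported for captive zebra finches — female-biased incubation
(simulated daily care ≈ 0.74 female vs ≈ 0.35 male, emulating the
published 0.72 vs 0.39 pattern), brooding declining over provisioning days
3/10/17, a quadratic diurnal dip toward the day's edges, within-day
repeatabilities averaging ≈ 0.20 (1 h) and ≈ 0.33 (3 h), and feeding split
evenly between sexes. `sim_config()` with defaults is the *neutral* world
(no individual variance, no diurnal term, no coupling) whose care occupancy
is checked against the closed-form stationary distribution of the 3-state
generator, and whose joint care factorizes into the product of the
marginals.

What the simulator does **not** emulate: autocorrelated "sessions" beyond
the exponential sojourns, weather/temperature drivers, brood-size effects
on feeding, observer error, or the forced night roosting outside lights-on
hours — recordings span 07:00–19:00 only, so that rule could never affect
an analysed interval; instead each recording burns in for one hour from a
baseline-stationary initial state. A green simulator-based test therefore
establishes that the estimators recover the structure of *this* stated
world, not that real zebra finches obey it.

## Study-design arithmetic

`scheduled_hours()` encodes the reference recording design — per stage
group of 10 nests: full days (12 h) early and late, 3 h mid-stage, plus the
provisioning group's extra 3 h mid-incubation recording — giving 570 h
against 840 h for the all-12 h alternative (32% less coding effort).

## Numerical and degenerate-input policy

* All-identical effort values: $F$ undefined; reported as not repeatable
  with a diagnostic note rather than NaN propagation.
* Zero within-group variance with distinct groups: $F = \infty$, $p = 0$,
  $r = 1$.
* Zero predictor variance in a window: $R^2$ missing with a flag; zero
  response variance: $R^2 = 0$ with a flag.
* Paired/one-sample $t$ with zero variance: an error, not a silent 0/0.
* Times are double-precision seconds; interval algebra is exact at that
  precision, and tests use integer-second fixtures so the rasterization
  oracle is itself exact.

## Known limitations

* Repeatability is ANOVA-based only; GLMM or Bayesian repeatability with
  CIs is out of scope.
* The bootstrap interval type is percentile (BCa not implemented); with 10
  nests any interval type is rough.
* The published feeding-ratio repeatabilities came from an unbalanced
  design whose effective group size is not recoverable from the printed
  $F$; reconstruction tests cover duration metrics (see the package's
  acceptance suite).
* The CLI ingests the package's own CSV dialect; mapping a coding-software
  export onto it is a documented column-mapping exercise, not code.
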