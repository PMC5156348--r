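# nestbudget

Quantifying biparental care from nest-box event logs, and deciding how much
video you actually need to code.

Behavioural studies of biparental birds (the captive zebra finch is the
standard model) code nest-box video into event logs: per-parent intervals of
*care* (incubation, or brooding after hatching) and of being *inside* the
box, plus feeding bouts as point events. Researchers then face two linked
questions. First, measurement: individual, joint (both parents
simultaneously) and total (at least one parent) effort are interval-set
quantities that must be computed exactly, with footage gaps handled
honestly. Second, sampling design: coding video is expensive, so is a
single 1 h or 3 h window a reliable stand-in for a full 12 h day?

`nestbudget` implements the full pipeline:

* **Interval algebra** — exact union/intersection/difference on half-open
  `[start, end)` second intervals; attendance = care ∪ inside; joint =
  male ∩ female; total = male ∪ female; occupied/observable effort
  proportions in arbitrary windows, with gap-aware denominators.
* **Sampling windows** — fixed 1 h / 3 h tilings of a recording, per-metric
  effort matrices (nests × windows) and daily summaries.
* **Repeatability** — one-way ANOVA intraclass repeatability (Harper's
  variance-component method): `r = s²_A / (s²_A + MS_W)` with effective
  group size `n0 = (N − Σn_i²/N)/(k−1)`, reducing to
  `r = (F−1)/(F+n−1)` for balanced designs; paired 1 h-vs-3 h comparisons
  on 2-dp estimates, as published tables do.
* **Prediction accuracy** — per-window OLS `R²` of daily effort on window
  effort, with percentile bootstrap CIs (nests resampled, 10⁴ replicates,
  seed-deterministic).
* **Mixed models** — AIC-selected polynomial diurnal trends and
  sex × stage division-of-labour models (lme4, ML fits, likelihood-ratio
  tests).
* **Simulator** — a continuous-time two-parent three-state
  (off/inside/care) process with diurnal modulation, stage effects,
  individual random intercepts, partner coupling and Poisson feeding, so
  every estimator can be validated against known truth.

## Worked example

```r
library(nestbudget)

cfg  <- preset_paperlike(n_nests = 10, seed = 7)   # calibrated stated world
recs <- simulate_population(cfg)                   # 570 h reference design
inc3 <- Filter(function(r) r$stage == "incubation" && r$stage_day == 3, recs)

metrics <- c("male_care", "female_care", "joint_care", "total_care")
tab1 <- repeatability_table(lapply(metrics, \(m) effort_matrix(inc3, m, 1)))
tab3 <- repeatability_table(lapply(metrics, \(m) effort_matrix(inc3, m, 3)))
cbind(tab1[, c("metric", "r", "F", "df1", "df2", "p")], r3 = tab3$r)
#>        metric     r     F df1 df2        p    r3
#> 1   male_care 0.430 10.06   9 110 3.69e-11 0.628
#> 2 female_care 0.294  6.00   9 110 8.28e-07 0.468
#> 3  joint_care 0.322  6.70   9 110 1.31e-07 0.559
#> 4  total_care 0.357  7.66   9 110 1.15e-08 0.524

wc <- window_width_comparison(tab1$r, tab3$r)
#> mean r: 1h 0.35 vs 3h 0.55, paired t(3) = -11.42, p = 0.0014
```

Every metric is significantly repeatable within the day (df 9,110: 10 nests
× 12 one-hour windows), and 3 h windows are systematically more repeatable
than 1 h windows — the simulated corpus reproduces the qualitative design
conclusion that longer single windows give more trustworthy effort
estimates. The simulated division of labour is female-biased, as in the
real population:

```r
mean(sapply(inc3, daily_effort, metric = "female_care"))  # 0.62
mean(sapply(inc3, daily_effort, metric = "male_care"))    # 0.38

prediction_table(inc3, "joint_care", widths = 3, B = 2000, seed = 7)[,
  c("window_index", "R2", "ci_low", "ci_high", "p")]
#>   window_index   R2 ci_low ci_high       p
#> 1            1 0.73   0.41    0.96 1.8e-03
#> 2            2 0.91   0.79    0.99 1.9e-05
#> 3            3 0.83   0.69    0.97 2.2e-04
#> 4            4 0.71   0.36    0.96 2.2e-03
```

Each 3 h window predicts daily joint care well (R² 0.71–0.91) regardless of
time of day. Published balanced ANOVA tables can be converted directly:

```r
harper_r_from_f(4.68, k = 10, n = 12)  # 0.23 (male incubation, day 3, 1h)
scheduled_hours(10, "actual")          # 570 h, vs all-12h:
scheduled_hours(10, "all12h")          # 840 h
```

## Command line

```sh
Rscript -e 'nestbudget::nb_cli()' simulate --preset paperlike --seed 7 --output-dir out
Rscript -e 'nestbudget::nb_cli()' report --input out/corpus.csv --bootstrap 10000 \
    --seed 7 --output-dir out
```

`report` runs the whole chain (effort summaries, repeatability tables with
the 1 h-vs-3 h paired test, prediction tables, diurnal and
division-of-labour models) and writes schema-stable CSVs plus a JSON run
manifest per command.

## Documentation

The methods vignette (`vignettes/nestbudget-methods.Rmd`) documents the
model and estimators, the simulator's stated world and what it does and
does not emulate, numerical/degenerate-input policy, and known limitations.
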