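# fcmonitor

Design and evaluation of preharvest monitoring for false codling moth
(FCM, *Thaumatotibia leucotreta*) fruit infestation in citrus orchards.

FCM is a quarantine pest for several citrus export markets. Under the
systems approach used for export risk mitigation, orchards are monitored
for the last ~12 weeks before harvest and compared against an action
threshold of **0.1 infested fruit per tree per week**, measured on fallen
fruit (every infested fruit abscises, so the fallen-fruit census is an
absolute measurement, not a sample). Two monitoring protocols are of
interest:

* the *five-data-tree* protocol: four marked sets of five trees, one set
  centred in each orchard quadrant, whose fallen fruit are dissected
  separately; and
* a *sanitation-sample* protocol: a fixed-size sample of fruit drawn from
  the whole-orchard sanitation collection.

`fcmonitor` provides the pieces needed to study both:

* **Synthetic orchards** (`orchard_config()`, `generate_orchard()`,
  `select_data_trees()`, `collect_lots()`): rectangular tree grids,
  Poisson fruit drop (default 0.84 fruit/tree/week), negative-binomial
  per-tree infestation with a tunable clumping shape `k`, an optional
  centre-elevated (wind-shelter) gradient, and fruit crated in collection
  order into lots of 10 or 20.
* **The monitoring metric** (`infestation_rate()`, `compare_protocols()`,
  `table4_summary()`, `cumulative_sample_curve()`): infested fruit / trees
  / weeks, strict threshold exceedance, data-tree versus whole-orchard
  comparisons, and the cumulative first-*n*-fruit curve.
* **Sample sizes** (`watson_n()`, `population_size()`): the Watson
  finite-population formula
  `n = [P(1-P) / (A²/Z² + P(1-P)/N)] / R`, with the weekly fruit
  population `N = area × trees/ha × drop rate`, plus the worst-case
  harvest calculators (`harvest_infestation_pct()`, `fruit_per_tree()`).
* **Sampling coverage by Monte Carlo** (`ci_lower_bound()`,
  `resample_adequacy()`, `coverage_curve()`, `minimal_adequate_n()`):
  subsamples drawn with replacement from a census are *adequate* when
  their infested proportion reaches the lower bound of the census's 95%
  Wilson interval; coverage is the fraction of adequate iterations.
* **Dispersion and trend** (`mean_variance_ratio()`, `fit_count_model()`,
  `dispersion_test()`, `dispersion_table()`, `trend_test()`): per-lot
  infested counts with a log fruit-count offset, Poisson versus negative
  binomial compared by likelihood ratio (df 1), and a
  negative-binomial week-trend with orchard fixed effects.
* **I/O and pipeline** (`write_lots_csv()`, `load_census_csv()`,
  `fcm_table()`, `run_evaluation()`): CSV interchange, the published
  reference tables as fixtures, and a seeded end-to-end evaluation run.

## Worked example

```r
library(fcmonitor)

# How many sanitation fruit must be dissected on a 1.5 ha orchard
# (505 trees/ha, 0.84 fruit/tree/week) for 5% precision, 95% confidence?
watson_n(population_size(1.5, 505, 0.84))
#> [1] 240

# A 9-week season on an above-threshold 800-tree block with a mild
# centre-elevated gradient:
cfg <- orchard_config("block-7", n_rows = 20, trees_per_row = 40, n_weeks = 9,
                      mean_drop = 0.84, infestation_rate = 0.15,
                      gradient_strength = 2, seed = 2024)
records <- generate_orchard(cfg)
cmp <- compare_protocols(records, threshold = 0.1)
round(head(cmp[, c("week", "set_a", "set_b", "set_c", "set_d",
                   "all_sets", "whole_orchard")], 4), 2)
#>   week set_a set_b set_c set_d all_sets whole_orchard
#> 1    1   0.2   0.0   0.0   0.0     0.05          0.16
#> 2    2   0.0   0.0   0.2   0.0     0.05          0.16
#> 3    3   0.0   0.2   0.2   0.2     0.15          0.13
#> 4    4   0.4   0.2   0.6   0.2     0.35          0.15

round(table4_summary(cmp), 2)
#>          pct_set_ge_orchard         pct_weeks_no_set_ge
#>                          50                           0
#> pct_cases_missed_exceedance pct_weeks_missed_exceedance
#>                          50                           0
```

Individual five-tree sets are noisy (half the set-weeks here sit below the
orchard rate, and half of the set-week cases miss an orchard exceedance),
but in *every* week at least one set matched or beat the orchard rate and
at least one set flagged the exceedance
(`pct_weeks_no_set_ge = pct_weeks_missed_exceedance = 0`).

```r
# Sampling coverage of subsample sizes, pooled over the 9 weekly censuses
censuses <- collect_season(records, lot_size = 20, seed = 2024)
curve <- coverage_curve(censuses, sample_sizes = seq(50, 500, 50),
                        iterations = 4999, seed = 2024)
minimal_adequate_n(curve, 0.90)
#> [1] 350

# First-100-fruit check of week 1 (644 fruit, 128 infested, rate 0.16):
cen1 <- censuses[[1]]
round(cumulative_sample_curve(cen1, n_grid = c(50, 100, 200))[,
      c("n", "proportion", "extrapolated_rate")], 3)
#>     n proportion extrapolated_rate
#> 1  50       0.08             0.064
#> 2 100       0.14             0.113
#> 3 200       0.16             0.129
```

The first 100 fruit of the sanitation collection already extrapolate to
0.113 infested fruit/tree — above the 0.1 threshold the full census
confirms (0.16).

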