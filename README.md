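# ecolag

Detects **ecological time lags** — delays between environmental change and
the population trends it drives — in Living Planet Database style abundance
records for birds and mammals, and projects what those lags imply for
abundance to 2050.

Population abundance often keeps responding to habitat conversion or climate
warming years to decades after the fact (extinction debt). Regressions of
biodiversity change on concurrent environmental change can therefore
misattribute or miss drivers entirely. `ecolag` is for ecologists and
conservation modellers who want to estimate those delays explicitly.

## The method

1. **Population trends.** Each abundance time series (span ≥ 5 years, ≥ 3
   points) is pre-processed (zeros → 1% of the non-zero mean; +1 shift for
   sub-unit series), interpolated annually on the log10 scale (linear
   interpolation below six points, a thin-plate GAM with basis dimension
   ⌈n/2⌉ otherwise), and summarized by the mean annual log10 rate of change

   λ̄ = Σₜ log₁₀(Nₜ/Nₜ₋₁) / (T − 1) = (log₁₀ N_T − log₁₀ N₁)/(T − 1).

   Trends with adjusted R² ≤ 0 are discarded.

2. **Lagged driver rates.** Rates of climate change (CC, OLS slope of mean
   annual temperature, °C/yr) and land-use change (LUC, mean annual change
   in the cropland+pasture+rangeland fraction) are computed over each
   population's monitoring window shifted back by a lag — 0–49 whole years,
   or 0.3–3.1 (birds) / 0.3–2.3 (mammals) species generation lengths
   converted to whole years.

3. **Lag-grid model scan.** At every CC × LUC lag combination (3341 for
   birds, 2941 for mammals on the full grids) a linear mixed-effects model
   λ̄ ~ CC\*LUC + BM + PA (+ Man + Use + Realm, per structure) with crossed
   random intercepts for species and location is fitted by ML, ranked by
   AICc and weighted by Akaike weight. The ΔAICc < 6 set is retained; its
   renormalized weights give model-averaged coefficients and per-lag support
   profiles whose mode is the best-supported lag.

4. **Projection.** Retained models project decadal abundance indices from
   2010 under three diverging environmental scenarios,
   I_d = I_{d−1} · 10^(10 λ̄_d), with each decade tagged by whether its
   lagged window predates 2010 (trend "locked in") or not.

A synthetic-data generator (`simulate_lpd()`) emulates the statistical
structure of the real inputs with known ground-truth lags and effect sizes,
so the whole pipeline is testable offline.

## Worked example

```r
library(ecolag)

cfg <- sim_config(n_species = 60, pops_per_species = c(2, 2), seed = 7)
sim <- simulate_lpd(cfg)                 # populations + environment + truth
trends <- quality_filter(population_trends(sim$populations))
scan <- lag_scan(trends, sim$populations$meta, sim$environment,
                 structure = "MU",
                 grid = lag_grid("bird", "years", year_lags = 0:10))
summary(scan)
```

```
Lag scan summary (structure MU )
  121 lag combinations, 5 retained (delta AICc < 6)
  best-supported lags: CC = 6, LUC = 2 (years)
  model-averaged coefficients:
            Estimate Std. Error
(Intercept) -0.01523    0.00355
CC          -0.02425    0.00204
LUC         -0.01095    0.00204
BM          -0.00310    0.00226
PA           0.02154    0.00395
Man          0.02442    0.00447
Use         -0.02583    0.00446
CC:LUC      -0.00623    0.00207
```

This dataset was generated with a 6-year climate lag and a 2-year land-use
lag, and the scan's best-supported lags are exactly 6 and 2 years. The
negative CC, LUC and CC:LUC coefficients say that faster (lagged) warming
and land conversion, especially together, predict declining trends. The use
coefficient (-0.026 log10 units/yr ~ -5.8% abundance per year) is well past
the IUCN Vulnerable decline rate and approaching the Endangered one
(`iucn_threshold_lambda(0.3) ~ -0.0155`, `iucn_threshold_lambda(0.5) ~
-0.0301`), while management and protection are associated with positive
trends.

```r
proj <- project_index(scan, trends, sim$populations$meta, sim$environment)
head(proj, 4)
```

```
    scenario decade_start decade_end    lambda  index cc_dependence luc_dependence
1 ssp1_rcp26         2010       2020 0.0060822 1.1503     partially      partially
2 ssp1_rcp26         2020       2030 0.0126814 1.5404           not            not
3 ssp1_rcp26         2030       2040 0.0159489 2.2239           not            not
4 ssp1_rcp26         2040       2050 0.0226657 3.7478           not            not
```

The index starts at 1 in 2010 and multiplies by 10^(10*lambda) per decade;
the `*_dependence` tags say whether each decade's lagged environmental
window lies before 2010 (and is therefore insensitive to the scenario
chosen).

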