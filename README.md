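# heatfootprint

Heat-stress disaster footprints across global supply chains: an integrated
climate–epidemiology–economy pipeline in R.

Extreme heat causes economic losses through three channels: excess deaths
during heatwaves, lost work capacity (especially heavy outdoor work), and
the propagation of those labour shocks through supplier–client networks.
**heatfootprint** implements the full chain for analysts of climate impacts:

* **Exposure.** Simplified wet bulb globe temperature from temperature and
  humidity, `WBGT = 0.567·Tₐ + 3.94 + 0.393·E` with
  `E = RH/100 · 6.105 · exp(17.27·Tₐ/(237.7+Tₐ))`; indoor exposure is
  `WBGT − 4`.  Heatwaves are ≥ 2 consecutive days strictly above the cell's
  95th-percentile baseline threshold (dynamic expanding-window and
  97.5 %/4-day variants included), counted as annual heatwave days (HWN).
* **Health.** Excess deaths `D = POP · MR · (RR − 1) · HWN` with
  climate-zone relative risks, monetized by a value of statistical life
  transferred with income elasticity 1.0 (equal-valuation mode available).
* **Labour.** Daily capacity loss `½(1 + erf((W − Prod_mean)/(Prod_SD·√2)))`
  per ISO work-intensity class (200/300/400 W), the 4+4+4 workday
  approximation, air-conditioning protection for indoor work, and
  hemisphere-specific warm-season windows, aggregated to region–sector
  shock series γᴸ(t).
* **Economy.** An adaptive multiregional input–output simulator: constrained
  Leontief production, proportional rationing, inventory and order dynamics
  on a network calibrated from a balanced MRIO table; losses decompose as
  `TEF = DEF + PEF` (total = direct + propagated value-added shortfall).
* **Synthetic data.** Licensed trade tables and large climate ensembles
  cannot be redistributed, so a first-class generator module produces
  climate grids (seasonal cycle, AR(1) anomalies, warming trends),
  population fields and RAS-balanced MRIO tables with the statistical
  structure the analysis assumes.  The whole pipeline runs and is tested
  offline.

## Worked example

```r
library(heatfootprint)
res <- runPipeline("mid", seed = 1)   # 5 regions x 4 sectors, 30-yr climate
print(res$report, digits = 3)
#>   region healthLoss directLoss indirectLoss totalLoss healthShareGDP
#> 1     R1   5.81e+08   2.74e+10     2.25e+10  5.05e+10        0.00167
#> 2     R2   6.86e+08   4.46e+10     1.33e+10  5.86e+10        0.00162
#> 3     R3   1.06e+09   1.73e+10     2.35e+10  4.18e+10        0.00266
#> 4     R4   1.75e+09   3.04e+10     1.51e+10  4.72e+10        0.00342
#> 5     R5   4.21e+09   2.29e+10     2.11e+10  4.82e+10        0.01088
#> 6  World   8.29e+09   1.43e+11     9.55e+10  2.46e+11        0.00401
#>   directShareGDP indirectShareGDP totalShareGDP
#> 1         0.0790           0.0647        0.1454
#> ...
#> 6         0.0690           0.0462        0.1192
```

Reading the `World` row: on this synthetic mid-warming world the final
simulated year costs 11.9 % of baseline GDP in total — 0.4 % from monetized
heatwave mortality (`healthLoss`, 2,532 excess deaths priced at
income-scaled VSLs), 6.9 % from labour capacity lost directly to heat
(`directLoss` = DEF), and 4.6 % propagated through supply chains to firms
that were not themselves constrained (`indirectLoss` = PEF).  Regions differ
through their climate, population and position in the trade network; the
synthetic tropics (high base temperature, low income, outdoor-heavy
sectors) lose most.  Magnitudes are properties of the synthetic world, not
projections.

Every stage is exposed on its own (`generateClimate()`, `computeWBGT()`,
`detectHeatwaves()`, `excessDeaths()`, `aggregateGamma()`,
`calibrateNetwork()`, `runFootprint()`, `decomposeLosses()`,
`monteCarloPipeline()`), and a thin command-line wrapper lives at
`inst/scripts/heatfootprint.R` (subcommands `generate`, `exposure`,
`simulate`, `run`, `montecarlo`).  See the vignette
`vignettes/heat-disaster-footprint.Rmd` for the model, its assumptions and
design decisions.

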