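---
title: "Modelling heat-stress disaster footprints across supply chains"
author: "heatfootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-stress disaster footprints across supply chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatfootprint)
```

# The problem

Extreme heat damages economies through three channels: people die during
heatwaves; workers — especially in heavy outdoor occupations — lose part of
their daily work capacity; and those capacity losses ripple outward through
supply chains, depressing production in firms that were never themselves
exposed.  **heatfootprint** implements that full chain as a reusable,
testable pipeline: gridded daily climate → heat-stress exposure → mortality
and labour-capacity losses → shock propagation on a multiregional
input–output network, with an additive decomposition of the total loss into
a *health* component, a *direct* labour component, and an *indirect*
(supply-chain) component.

Real applications of this model class rest on licensed trade databases and
multi-model climate ensembles.  Neither can be redistributed, so the package
ships a first-class synthetic-data module that generates inputs with the
statistical structure the analysis assumes.  Every stage runs, and is
tested, end to end on those synthetic worlds; conclusions about any real
economy require substituting real inputs.

# Heat-stress exposure

Exposure is measured by the simplified wet bulb globe temperature, computed
from near-surface air temperature $T_a$ (°C) and relative humidity RH (%):

$$\mathrm{WBGT} = 0.567\,T_a + 3.94 + 0.393\,E, \qquad
  E = \frac{\mathrm{RH}}{100} \times 6.105 \times
      \exp\!\left(17.27\,\frac{T_a}{237.7+T_a}\right),$$

dropping solar-radiation and wind terms, which are uncertain and weak at
global scale.  Indoor exposure deducts the radiative contribution as a fixed
offset, $\mathrm{WBGT}_{indoor} = \mathrm{WBGT}_{outdoor} - 4$.

A workday of 12 h is approximated by three four-hour blocks at
$\mathrm{WBGT}_{max}$, $\mathrm{WBGT}_{mean}$ and their midpoint (the
"4+4+4" rule); `computeWBGT()` evaluates the triplet from daily mean and
maximum temperature with the day's humidity.  Day length is fixed at 12 h;
no latitude-dependent daylight is modelled.

## Heatwaves

The benchmark heatwave definition is **two or more consecutive days with
daily mean temperature strictly above the cell's 95th-percentile
threshold**, the threshold being the empirical percentile of all daily means
in a fixed baseline window.  Design choices a user should know:

* the percentile estimator interpolates linearly between closest order
  statistics (`quantile(type = 7)`), pinned for reproducibility;
* comparison is strict (`>`): ties at the threshold are not exceedances;
* runs may cross calendar-year boundaries; each day is attributed to its own
  year, so annual heatwave-day counts (HWN) are additive;
* a *dynamic* variant recomputes the threshold for target year $y$ over the
  expanding window from the baseline start through $y-1$ — a simple
  representation of acclimatization under warming (a year's threshold never
  sees that year's data);
* a sensitivity preset uses the 97.5th percentile with 4-day minimum runs.

# Health losses

Excess deaths at a grid cell are

$$D_{hw} = \mathrm{POP} \times \mathrm{MR} \times (\mathrm{RR}-1) \times
  \mathrm{HWN},$$

with POP the cell population, MR the baseline daily mortality rate, RR the
relative risk of mortality on heatwave days for the cell's climate zone, and
HWN the annual heatwave days.  The form is linear in each factor, so cells
aggregate to regions by summation.  Zone-specific RR values are
*configuration inputs*: the packaged four-zone table
(`illustrativeRRTable()`, and `inst/extdata/rr_table_synthetic.csv`) is an
illustrative placeholder, not an epidemiological estimate, and
`assignClimateZones()` is a reproducible stand-in that cuts cells into
quartile zones of baseline warm-season temperature.  Both are overridable
from files.

Deaths are monetized with the value of a statistical life (VSL): an anchor
VSL of US\$11 million (2019) at an anchor income of US\$65,000/yr,
transferred across regions with income elasticity 1.0,
$VSL_r = VSL_a (y_r/y_a)^{\epsilon}$.  An `equal_world` mode instead applies
the population-weighted mean of the income-scaled VSLs to every region — the
equal-valuation sensitivity.  A single configurable deflator handles price
bases.

# Labour losses

Daily work-capacity loss follows the cumulative-normal exposure-response
curve

$$L(W) = \tfrac12\!\left(1 + \mathrm{erf}\!\left(
  \frac{W - \mathrm{Prod}_{mean}}{\mathrm{Prod}_{SD}\sqrt{2}}\right)\right),$$

the benchmark; the logistic "Hothaps" workability curve
$0.1 + 0.9/(1+(W/\alpha_1)^{\alpha_2})$ is exposed as a sensitivity
alternative (its loss is one minus workability; it spans $(0.1, 1]$, i.e. at
extreme heat 10% workability remains).  Three ISO work-intensity classes are
mapped to sectors: 200 W light indoor work (services), 300 W moderate indoor
work (industry), 400 W heavy outdoor work (construction, agriculture).  The
class parameters shipped in `inst/extdata/intensity_map_synthetic.yaml` are
placeholders to be replaced by study estimates.

Indoor work can be protected by air conditioning.  Penetration is a
climate-driven saturation level times an income logistic,
$$pen = satMax\,(1-e^{-\max(C-C_0,0)/s}) \cdot
  \mathrm{logit}^{-1}\!\big(k(\log y - \log y_{1/2})\big),$$
with $C$ the indoor-WBGT warm-season climatology.  The published
climate–income–air-conditioning relationship this emulates is not specified
in closed form in the sources available to us; the logistic form here is an
explicit design choice with the right qualitative behaviour (monotone in
income and in climate, zero at zero income, saturating in hot climates), and
its parameters are user-facing (`acModel()`).

`aggregateGamma()` builds the climate-to-economy bridge
$\gamma^L_{r,s}(t)$: the population-weighted regional mean of the effective
daily loss for each sector's intensity class, masked to the warm season —
June–September north of the equator, December–March south of it (cells
within 1° of the equator follow the northern window by convention; the
convention is configurable by overriding cell latitudes).  Outside the
window $\gamma^L = 0$: the shock model is designed for acute seasonal heat
stress, not mild year-round warming.  Heat mortality is deliberately *not*
fed into $\gamma^L$; the health and labour channels stay separate and are
added in the final report.

# The supply-chain simulator

The economic core is an adaptive multiregional input–output simulation.
Calibration (`calibrateNetwork()`) treats each region–sector pair as a firm
and each region as one representative household, and divides annual flows by
the number of steps (default 365 daily steps), so one no-shock step
reproduces the equilibrium exactly and per-step baseline value added times
the horizon equals annual value added.  Product classes coincide with
sectors; input coefficients $a_i^p = \bar z_i^p/\bar x_i$ and value-added
coefficients $b_i = \bar{va}_i/\bar x_i$ satisfy $\sum_p a_i^p + b_i = 1$.

Each step executes, in order:

1. **Production.** Capacity is the scarcest input (Leontief):
   $x_i^{max}(t) = \min\big((1-\gamma^L_i)\bar x_i,\ (1-\gamma^K_i)\bar x_i,\
   \min_p S_i^p(t\!-\!1)/a_i^p\big)$; products with $a_i^p = 0$ never
   constrain.  Actual output is capped by the orders received last step,
   $x_i^a = \min(x_i^{max}, TOD_i(t\!-\!1))$, and draws down inventories by
   $a_i^p x_i^a$.
2. **Order issuing.** Each firm targets an inventory of $n$ steps of cover
   at current capacity, $S^{p,*} = n\,a^p x^{max}(t)$, and orders the gap
   above its *post-use, pre-receipt* inventory position, split across the
   suppliers of product $p$ proportionally to baseline flow times relative
   capacity $(x_j^a/\bar x_j)^\psi$ (renormalized; if every candidate
   supplier is at zero output, baseline shares are used).  Households order
   their exogenous demand the same way.  The exponent $\psi$ spans fixed
   baseline sourcing ($\psi = 0$) to strongly capacity-chasing substitution
   ($\psi > 1$); default 1.
3. **Allocation.** Output is rationed to last step's orders proportionally;
   allocations sum exactly to $x^a$, zero total orders allocate nothing, and
   unmet household demand is simply lost (no backlog).
4. **Restoration.** Receipts accrue to the client's inventory of the
   supplier's product class.

Two timing conventions deserve note, both resolved in favour of making the
no-shock trajectory an *exact* fixed point (which the test suite asserts to
1e-8 over 100 steps on 200-firm networks): goods received in a step become
usable the following step, and order decisions see the inventory position
before that step's receipts.  Similarly, the capacity weight in order
reallocation uses the supplier's *relative* utilization $x_j^a/\bar x_j$
rather than absolute output — absolute weighting would distort equilibrium
order shares whenever suppliers differ in size.

## Footprint accounting

With $va^a_i(t) = b_i x^a_i(t)$ and $va^{max}_i(t) = b_i\,
\min(x^{max}_i(t), \bar x_i)$, the per-firm footprints over horizon $T$ are

$$TEF_i = \bar{va}_i T - \sum_t va^a_i(t), \qquad
  DEF_i = \bar{va}_i T - \sum_t va^{max}_i(t), \qquad
  PEF_i = TEF_i - DEF_i .$$

$DEF$ is the direct loss the firm's own capacity constraints impose; $PEF$
is the propagated (supply-chain) remainder.  With shocks in $[0,1]$ and no
overproduction, $x^a \le x^{max} \le \bar x$ pointwise, hence
$TEF \ge DEF \ge 0$ and $PEF \ge 0$.  The cap of $va^{max}$ at baseline
makes $DEF$ a shortfall measure even when ample inventories would permit
$x^{max} > \bar x$ under an overproduction factor.

## Dynamics worth knowing about

The order rule couples the inventory *target* to current capacity,
$S^* = n\,a\,x^{max}(t)$.  A capacity dip of magnitude $m$ therefore cuts
orders by roughly $n \times m$ times the replacement rate — a bullwhip with
gain $n$.  Two consequences, both verified by the test suite on the packaged
synthetic worlds: indirect losses are substantial already for small shocks,
and the indirect *share* $PEF/TEF$ tends to fall, not rise, as a fixed shock
pattern is scaled up uniformly (direct losses grow linearly while the
order-driven indirect response saturates).  Growth of the indirect share
across scenarios therefore has to come from the climate side — more regions
shocked, longer and co-occurring events — not from deepening a fixed shock.
Analysts comparing scenarios should keep this decomposition behaviour in
mind.

# The synthetic-data module

`generateClimate()` emulates what the downstream stages need from a climate
ensemble: a seasonal cycle with hemisphere-dependent phase (warm peak in
July north of the equator, January south), AR(1)-autocorrelated daily
anomalies (innovation SD and lag-1 coefficient configurable; the
configured coefficient is recovered from long runs within ±0.02 by the
tests), a linear secular warming trend per scenario, daily maxima a fixed
diurnal half-range above the mean, and relative humidity co-varying linearly
with the temperature anomaly, clipped to [0, 100].  It deliberately does
*not* emulate spatial anomaly correlation, specific models' climate
sensitivity, bias structures, or humidity extremes — so passing tests
demonstrate correct mechanics, not climate realism.  A 365-day no-leap
calendar is used throughout, as is conventional for long model runs.
Scenario labels are neutral (`low`/`mid`/`high`, 0.15/0.35/0.75 °C per
decade) to avoid implying fidelity to any published forcing pathway.

`generatePopulation()` draws Gamma-distributed cell weights (concentration
parameter `clustering`; 0 gives an exactly uniform field) and apportions the
world total by largest remainder, so totals are conserved exactly; regions
are contiguous longitude bands with per-region mortality and income.

`generateMRIO()` draws gross outputs, value-added and final-demand shares,
then balances a random-support flow matrix to the implied row/column totals
by iterative proportional fitting (RAS), guaranteeing both accounting
identities to a relative residual below 1e-8 — the property the simulator's
equilibrium calibration relies on.  Within-sector self-supply is always kept
so the fitting problem has support.  In `runPipeline()` the table is
uniformly rescaled so world value added equals the synthetic population's
aggregate income, putting mortality valuation and production losses in the
same monetary units.

All generators are pure functions of their configuration (including the
seed): identical configs give bit-identical outputs.

# Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `percentile`, `minRun` | heatwave rule | 95%, 2 days | 97.5%/4 preset |
| baseline window | threshold years | 20 synthetic years | configurable |
| `prodMean`, `prodSD` | loss curve, °C-WBGT | per class | placeholders |
| `alpha1`, `alpha2` | Hothaps curve | per class | placeholders |
| `anchorVSL` | VSL anchor, USD | 11e6 | 2019 USD |
| `incomeElasticity` | VSL transfer | 1.0 | `equal_world` mode |
| `nTarget` | inventory cover, steps | 15 | Monte Carlo 10–30 |
| `substitutionExponent` | sourcing response | 1 | 0 = fixed shares |
| `overproduction` | spare capacity factor | 1 | ≥ 1 |
| `horizon` | steps per run | 365 daily | flows split evenly |

# Numerical and scale choices

Simulations in the tests and examples run at desk scale by design: 6×10
climate grids over 10–30 synthetic years, 5 regions × 4 sectors (20 firms)
for pipeline runs, up to 20 regions × 10 sectors (200 firms) for equilibrium
checks, one-year daily horizons.  The pipeline is linear-time in cells ×
days and the simulator in steps × firms², so larger worlds scale
predictably.  Degenerate inputs are handled explicitly: zero total orders
allocate zero; products a firm does not use never constrain it; zero-output
firms are rejected at calibration; non-finite state aborts the simulation
with a diagnostic.

# Limitations

No age- or humidity-dependent mortality risk, no morbidity costs, no
capital-reconstruction or price dynamics, no trade-structure change across
scenarios, no mechanization response, and no transport disruption.  Heat
mortality does not reduce labour supply.  These mirror the stated boundaries
of the model class; the packaged defaults are placeholders wherever the
underlying empirical constants are not public.
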