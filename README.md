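# fdpscan

Movement ecologists studying free-ranging scavengers can rarely observe
meals directly. `fdpscan` infers them from biologging data: GPS fixes
(position + instantaneous ground speed on a 10-min diurnal duty cycle)
and accelerometer bursts classified upstream into seven behaviours. From
these it reconstructs each animal's **food-deprivation periods (FDPs)** —
the whole days without a detected meal before each feeding event — and
tests how daily movement responds to mounting hunger. The motivating
system is a supplementary-fed griffon vulture population, where a
hump-shaped response of daily travel to days-since-feeding marks a switch
from food-intake maximisation to energy-expenditure minimisation around
day 5 of a fast.

## What it computes

- **Daily movement characteristics** per animal-day: activity (maximal
  displacement from the roost > 2 km), roost-departure offset after
  sunrise (first fix with speed > 4 m/s; left-censored when the bird left
  before the first sample), travelled distance, maximal displacement,
  straightness `2·Dmax/L`, mean flight speed and elevation, and ground
  **day-stops** (static within 400 m of a running centroid for > 20 min)
  with behaviour-label tallies.
- **Feeding events** from conservative stop rules: ≥ 2 `eating` bursts;
  or 1 `eating` + ≥ 2 `running`; or 1 `eating` co-located and
  co-temporal with another tagged animal's feeding stop; 1 `eating` +
  1 `running` is *undecided*. Stops in roost polygons never count.
- **FDP sequences** with the exclusion rules (unknown history, missing or
  undecided days inside the gap, FDP > 14 d), the FDP histogram and its
  negative-exponential fit `Y = A·e^(−bx)`.
- **Statistics**: per-vulture day-profile means (pseudo-replication
  control), constant/linear/quadratic model selection by AICc,
  hungry-vs-satiated paired contrasts with Benjamini–Yekutieli FDR
  control, and a balanced two-way repeated-measures ANOVA contrasting
  short (FDP 1–4) with long (FDP ≥ 6) sequences.
- **A calibrated synthetic generator** (`sim_config()`,
  `simulate_population()`) producing ground-truthed populations whose
  daily summaries match the study system's printed calibration values
  (52% zero-day FDPs, 90% active days, straightness 0.617, departure
  3 h after sunrise, hump peak at day 5, 71.4% of meals at feeding
  stations, winter long-FDP share 15%).

## Worked example

```r
library(fdpscan)

rep <- run_synthetic_pipeline(sim_config(n_vultures = 5, n_days = 80,
                                         seed = 7))
print(rep)
#> <fdp_report>
#>   animal-days: 400 (92.5% active)
#>   feeding days: 118; valid events: 110 (30.9% FDP = 0)
#>   straightness 0.636 | departure 3.12 h | exp rate 0.32

rep$models$travel_distance[, c("model", "aicc", "delta", "selected", "vertex")]
#>       model  aicc delta selected vertex
#> 1  constant 204.5 1.915    FALSE     NA
#> 2    linear 203.3 0.720    FALSE     NA
#> 3 quadratic 202.6 0.000     TRUE  5.808
```

Five birds over 80 days yield 400 animal-days, 92.5% of them active;
118 days carry a detected meal, and 110 events survive the FDP exclusion
rules. The day-profile fit selects the hump (quadratic) model for travel
distance with its peak near day 5 — even at this small scale the
AICc margin over the linear model is visible (Δ = 0.72). At the default
scale (20 × 200) the selection is unambiguous and the vertex lands within
half a day of 5. This run uses the seasonal calibration (winter months
feed more rarely), so its zero-FDP share sits near 31% rather than the
flat-rate 52%.

The numbered drivers under `analysis/` run the same workflow as a
file-based pipeline at the default scale and leave all tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # raw synthetic track tables
Rscript analysis/02_daily_metrics.R   # daily metrics + day-stops
Rscript analysis/03_feeding_events.R  # feeding events, FDPs, histogram
Rscript analysis/04_response_models.R # model selection, contrasts, ANOVA
```

## Package layout

- `R/` — generator (`synthgen`), daily metrics (`trackmetrics`), feeding
  and FDP assembly (`feedscan`), statistics (`fdpstats`), readers/writers
  and orchestration (`io`, `pipeline`).
- `analysis/` — the numbered workflow drivers.
- `vignettes/fdp-methods.Rmd` — the methods notes: model assumptions,
  thresholds, generator calibration, numerical choices, limitations.
- `tests/testthat/` — unit, property and end-to-end recovery suites.
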