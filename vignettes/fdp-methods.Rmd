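---
title: "Inferring food-deprivation periods and movement responses from biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring food-deprivation periods and movement responses from biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fdpscan` analyses how the movement of a large soaring scavenger changes
with hunger, using the number of days since the last detected meal — the
food-deprivation period (FDP) — as the hunger proxy. The pipeline takes
GPS fixes and accelerometer(ACC)-classified behaviour labels, detects
ground stops, classifies them as feeding or not, assembles per-event FDPs,
and asks whether daily movement characteristics follow a constant, linear
or hump-shaped profile along the days of a deprivation sequence.

This vignette documents the model and its assumptions, every tunable
threshold, what the synthetic generator emulates (and what it does not),
and the numerical choices made where the design was genuinely open.

## The measurement model

Tags sample a three-dimensional GPS position with instantaneous ground
speed every 10 minutes during a 12-h diurnal duty cycle, alongside short
ACC bursts classified upstream into seven behaviours: active (flapping)
flight, passive (soaring) flight, standing, lying, preening, running and
eating. The behaviour classifier itself is out of scope here — labels are
an input.

Daily movement characteristics, computed per animal-day after linear
interpolation of missing fixes onto the sampling grid:

- **Active day**: maximal displacement from the day's first location
  (the roost) strictly exceeds 2 km. Roughly one day in ten is inactive.
- **Roost departure**: hours from sunrise to the first fix with ground
  speed strictly above 4 m/s. If the first sample of the day is already
  non-static the departure is left-censored and excluded from averages.
- **Travel distance**: sum of planar distances between successive fixes.
- **Maximal displacement**: distance from the first to the farthest fix.
- **Straightness**: `2 * Dmax / L`, clipped to `[0, 1]` — exact for a
  straight out-and-back flight (see *Numerical choices*).
- **Travel speed / flight elevation**: means of speed and altitude over
  non-static fixes.
- **Day-stop**: a maximal run of fixes opening at a static fix, all
  within 400 m of the running centroid, spanning more than 20 minutes.

## Feeding classification and FDP assembly

A stop outside the major roost polygons is a **feeding stop** when
(i) it contains two or more `eating` bursts, (ii) one `eating` burst plus
two or more `running` bursts, or (iii) a single `eating` burst while
another tagged animal's feeding stop overlaps it in time within 400 m
(co-feeding). One `eating` with exactly one `running` is **undecided**.
Rule iii is resolved in a second pass against rule-i/ii feeders only,
which makes the outcome independent of animal processing order and keeps
the rule conservative (a lone eater cannot vouch for another lone eater).

Any feeding stop makes its animal-day a feeding day. The FDP of an event
is the count of whole non-feeding days since the animal's previous event.
An event is excluded when its history is unknown (first event per
animal), when a day strictly inside the gap is missing or carries an
undecided stop, or when the FDP exceeds 14 days (tag malfunction
territory). Each valid event opens an **FDP sequence**: day 0 is the
feeding day that starts the run, days 1..FDP are the hungry days before
the next event.

## Statistical analysis

*Day-profile model selection.* For each movement metric, values at day
`d` are first averaged within each vulture across its sequences (cells of
a vulture-by-day table), which controls pseudo-replication; sequences
longer than 10 days are excluded as too rare. Three nested response
models — `Y = C`, `Y = a + bX`, `Y = a + bX + cX²` — are fit by ordinary
least squares and compared with AICc, counting the residual variance as a
parameter (`k` = 2, 3, 4) and flooring the RSS at 1e-12 so that exact
synthetic fits stay finite. Ties within 1e-9 go to the simpler model. By
default the models are fit to the vulture-level cells; a
`fit_grand_means` switch fits the 11 per-day grand means instead. The
selection-consistency guarantees (quadratic selected under a strong hump,
constant under a flat profile) hold at the grand-mean scale, where the
small-sample AICc penalty is meaningful; at the cell scale the penalty
for one extra parameter is only about 2 units, so a flat profile is
over-fit in roughly a fifth of replicates — both paths are exposed, and
the consistency tests exercise the grand-mean path.

*Hungry versus satiated.* Each metric is compared between the day before
and the day after a feeding event (flanking days must exist, carry data,
and not themselves be feeding days), averaged per vulture on each side,
and tested with a paired t-test across vultures (a sign-permutation
variant is provided). The family of p-values is corrected with the
Benjamini–Yekutieli step-up procedure, valid under arbitrary dependence:
reject up to the largest `i` with `p_(i) <= i*alpha / (m * c(m))`,
`c(m) = sum(1/j)`.

*Short versus long sequences.* Vultures with at least three long
(FDP >= 6) sequences and three sequences of FDP exactly 4 enter a
balanced two-way repeated-measures ANOVA on days 1–4, with sequence type
and day as within-subject factors. Requiring FDP = 4 on the short side —
the inclusion rule's own phrasing — guarantees every compared day index
exists for every included sequence. Cell means per subject balance the
design; the classical sums-of-squares decomposition tests each factor
against its interaction with subjects. When an error stratum has zero
sum of squares the table carries a `degenerate` flag instead of
fabricating F statistics. The reported degrees of freedom follow the
standard balanced layout.

*FDP distribution.* The histogram of valid FDPs is fit with
`Y = A*exp(-b*x)` by count-weighted least squares of log counts — the
variance-stabilising weighting for Poisson-like counts, which keeps
near-empty tail bins from dominating the slope — with the coefficient of
determination computed on the count scale.

## The synthetic generator

No field dataset ships with the package, so a calibrated generator
produces populations whose *daily summaries* carry the statistical
structure the analysis assumes. Its defaults are the packaged field
calibration:

| parameter | default | meaning |
|---|---|---|
| `fix_interval` | 10 min | sampling grid within a 06:00–18:00 duty cycle |
| `p_missing_fix` | 0.10 | independent dropout per scheduled fix |
| `p_active_day` | 0.90 | marginal share of active days |
| `fdp_p0` | 0.52 | per-day feeding probability (non-seasonal) |
| `hump_peak_day` | 5 d | day-within-FDP of peak displacement |
| `hump_base`, `hump_gain` | 12, 8 km | displacement at the profile's floor and added at its peak |
| `tortuosity` | 1.62 | path length over round-trip displacement; expected straightness 1/1.62 = 0.617 |
| `departure_mean`, `departure_sd` | 3.0, 1.0 h | truncated-Normal departure after a fixed 05:42 sunrise |
| `speed_mean` | 10 m/s | cross-country ground speed of flight fixes |
| `elevation_base`, `elevation_gain` | 400, 200 m | flight altitude following the same hump |
| `stop_rate` | 1.5/day | non-roost loafing stops (Poisson, capped at 4) |
| `p_feed_at_sfs` | 0.714 | feeding stops at supplementary feeding stations |

Feeding is a memoryless daily process — each day an animal feeds with
probability `p` — so FDPs are geometric on `{0, 1, 2, ...}` with zero
fraction `p`, the maximum-entropy law behind an exponentially decaying
histogram. Seasonality replaces the flat `p` with a monthly value derived
from target monthly shares of long (>= 6 d) FDPs,
`p(m) = 1 - prop(m)^(1/6)`, with a winter maximum of 0.15, an
early-summer minimum of 0.05 and a secondary autumn bump. The flat and
seasonal calibrations are deliberately separate: a single geometric rate
cannot produce both a 52% zero fraction and winter months where 15% of
events follow six-plus hungry days, so the sampler default carries the
overall zero share while the seasonal table carries the monthly long-FDP
profile — each recovered by the analysis path that measures it.

An active day is an out-and-back flight: departure drawn after sunrise,
a displacement drawn from a Gamma around the hump profile for the
current day-within-FDP (floored at 5 km so apparent speeds at the 10-min
resolution stay above the static threshold), an outbound and an inbound
zigzag leg whose alternating headings make the path length `tortuosity`
times the displacement, Poisson loafing stops at flight vertices, and a
feeding stop at the turnaround on feeding days (at the station whose
distance best matches the drawn displacement, else at an occasional
carcass). Feeding days are always active — a bird that ate necessarily
left the roost — and non-feeding days are active with the probability
that restores the 0.90 marginal. Eating and running bursts are placed in
the early-to-mid part of a stop, as birds feed soon after landing; this
also keeps the classification robust to fix dropout at stop edges. When
several animals feed at one station with generously overlapping planned
windows, later arrivals may be emitted with a single `eating` burst,
exercising the co-feeding rule; loafing stops on feeding days go on the
inbound leg so planned arrival times hold.

What the generator does **not** emulate: terrain and thermals (flight is
planar with altitude drawn, not soared), GPS position error beyond
isotropic 15-m noise, social information transfer, meal size, tag
outages (whole missing days are supported by the pipeline but off by
default), and any within-day behavioural sequence beyond
roost–fly–stop–fly–roost. Passing the recovery tests therefore shows the
*pipeline* is correct and the calibration self-consistent — not that
real vultures behave like the generator.

## Numerical choices

- **Straightness convention.** A literal travel-distance over
  displacement ratio exceeds 1, yet reported daily straightness lies in
  `[0, 1]`; for birds that return to their roost each evening the
  natural reading is the round-trip efficiency `2*Dmax/L`, clipped at 1.
  The alternative (`Dmax` over the distance travelled up to the farthest
  point) is a config switch, not the default.
- **Strict boundaries.** Active iff displacement > 2 km; non-static iff
  speed > 4 m/s — both strict, mirroring the rules' phrasing; a fix at
  exactly 4 m/s is static.
- **Geometry.** All computation is in local planar metres. Geographic
  input is projected on read with a local flat-earth approximation using
  WGS84 curvature radii at the dataset centroid; length distortion at a
  100-km extent stays below 0.1%.
- **Interpolated fixes** carry the chord speed of their bracketing real
  fixes, so speed-based classification stays consistent with the
  interpolated positions. No extrapolation beyond the first or last real
  fix; a day with fewer than two real fixes is flagged missing.
- **Stop construction** is a single greedy left-to-right pass with a
  running centroid — the rule names a radius and a duration, not a
  clustering algorithm, and the greedy scan is deterministic and
  order-free.
- **Sunrise** is a per-day input table (fixed 05:42 by default in the
  generator) rather than an astronomical computation; only the offset
  from sunrise matters to the pipeline.
- **Undecided stops** invalidate only gaps they fall strictly inside;
  an undecided stop elsewhere on a feeding day does not invalidate the
  following gap. They never create events.
- **Problem sizes.** The packaged default population is 20 animals for
  200 days (about 290k fixes); recovery of the calibration values is
  well inside Monte-Carlo tolerance at this size, and the winter
  long-FDP share uses a full calendar year with a December burn-in so
  early-winter events carry complete histories.

## Known limitations

- The day-level collapse cannot represent two meals in one day, matching
  the FDP's day resolution but losing intra-day feeding structure.
- The co-feeding window (temporal overlap, 400 m) quantifies "same time
  and place" with declared defaults; they are config, not inferred.
- Flight elevation is altitude above sea level as recorded in the fix;
  above-ground elevation would need a terrain model.
- The repeated-measures ANOVA reports its own balanced-layout degrees of
  freedom; printed F-ratio subscripts in comparable field reports are
  not always reconcilable with a standard layout, and no attempt is made
  to mimic any particular one.
- With ~10% fix dropout, a stop's detected window can shed an edge slot;
  classification then relies on bursts away from the edges. Mid-stop
  burst placement in the generator reflects this; with real data a
  pathological stop whose only `eating` burst sits in a dropped edge
  slot would be missed.
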