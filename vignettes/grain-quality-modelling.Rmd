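---
title: "Modelling grain protein and starch accumulation in foxtail millet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grain protein and starch accumulation in foxtail millet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainqual)
```

## Scope and data flow

`grainqual` is a post-processor for daily crop-state trajectories over
grain filling. It does not grow the crop: phenology, photosynthesis, soil
water and nitrogen are the business of a process-based engine (or of this
package's synthetic generator, below). From anthesis (day 0) to maturity
the package takes, per day, the aboveground dry weight `topwt`, the
vegetative dry weight `vwt`, grain nitrogen `gna`, actual and potential
transpiration `ta`/`tp`, the plant nitrogen concentration `anp` with its
critical (`cnp`) and minimum (`mnp`) reference curves, and the mean air
temperature `tavg`; plus three scenario scalars: panicle density `sp`
(spikes/ha), grains per panicle `ng`, and the anthesis-to-maturity
thermal time `gdd_am`. From these it simulates daily grain protein,
starch, amylose and amylopectin accumulation.

## The protein module

Grain protein is grain nitrogen times a nitrogen-to-protein conversion
factor that responds to the plant's same-day water and nitrogen status:

$$\mathrm{GPA}_i = \mathrm{GNA}_i \cdot \mathrm{NPF}_i, \qquad
  \mathrm{NPF}_i = \delta \cdot \min[f(W_i), f(N_i)] + \mathrm{NPF}_0$$

$f(W) = T_a/T_p$ clamped to $[0,1]$; $f(N)$ ramps linearly from 0 at the
minimum plant N concentration to 1 at the critical concentration. The
binding (smaller) stress governs. With the calibrated values
$\mathrm{NPF}_0 = 5.83$ and $\delta = 0.18$ the factor is confined to
$[5.83, 6.01]$: a stressed crop converts nitrogen to protein at a lower
ratio. No smoothing or lag is applied — the factor is a memoryless
function of the day's stress — and day 0 is evaluated like any other day
so cumulative curves start at anthesis (where grain N is essentially
zero).

## The starch module

Per-grain starch accumulates by Michaelis–Menten kinetics in the day's
available carbon, throttled by an enzyme-activity factor:

$$\mathrm{ISTR}_i = \mathrm{ISTR}_m \cdot E_{act,i}
   \cdot \frac{\mathrm{GCA}_i}{K_m + \mathrm{GCA}_i}, \qquad
  \mathrm{IGSA}_i = \mathrm{IGSA}_{i-1} + \mathrm{ISTR}_i$$

scaled to the canopy as $\mathrm{GSA}_i = SP \cdot N_g \cdot
\mathrm{IGSA}_i \cdot 10^{-6}$ kg/ha.

**Carbon supply.** Before the remobilization onset — accumulated thermal
time below $\mathrm{GDD}_m$ — grains receive only the day's net canopy
growth not retained by vegetative organs
($\Delta\mathrm{TOPWT} - \Delta\mathrm{VWT}$). From the onset on they
receive all new aboveground growth plus the decline of vegetative dry
weight (remobilized reserves). Both fluxes are floored at zero before the
per-grain conversion $\mathrm{GCA}_i = 10^6(\mathrm{GCP}_i +
\mathrm{GCT}_i)/(SP \cdot N_g)$: senescence can drive the raw
differences negative, and a negative substrate is meaningless in the
kinetics. The raw signed values are kept in the `gcp_raw`/`gct_raw`
debug columns. Carbon not converted on its day does not pool over; the
supply is strictly same-day. The onset comparison uses
$\mathrm{GDD}_i \ge \mathrm{GDD}_m$ (the boundary day is post-onset),
consistent with the lifecycle decline starting strictly after the peak.

**Enzyme activity.** $E_{act} = f(\mathrm{GDD}) \cdot f(T) \cdot f(W)
\cdot f(N)$, four $[0,1]$ factors:

* *Lifecycle*: $(\mathrm{GDD}/\mathrm{GDD}_m)\,
  e^{\gamma(\mathrm{GDD}_m - \mathrm{GDD})}$ up to the peak at
  $\mathrm{GDD}_m$ (value 1), then a linear decline to 0 at
  $\mathrm{GDD}_{AM}$. The curve is clamped to $[0,1]$; with the
  calibrated $\gamma \cdot \mathrm{GDD}_m = 0.512 < 1$ the rising branch
  never exceeds 1 and the clamp is inert.
* *Temperature*: sine ramp from the minimum (7 °C) to the lower optimum
  (22 °C), plateau at 1 to the upper optimum (27 °C), sine fall to the
  maximum (60 °C), zero outside; continuous at all four cardinal points.
* The water and nitrogen stress factors shared with the protein module.

**Amylose partition.** The amylose share of *cumulative* starch is
$RA_i = (\alpha \ln \mathrm{GDD}_i - \beta) f(N_i)$, clamped to $[0,1]$
and set to 0 at $\mathrm{GDD} = 0$ to avoid $\ln 0$; then
$\mathrm{GASA} = \mathrm{GSA} \cdot RA$ and $\mathrm{GAPA} =
\mathrm{GSA}(1 - RA)$, which conserve mass by construction. Two
documented choices: $RA$ is treated as a fraction (the split multiplies
it directly, with no /100, so a percent reading would be dimensionally
inconsistent), and it is applied to the cumulative pool rather than to
daily increments — the literal reading of the accumulation equations.
Nitrogen stress lowers the amylose share, consistent with
amylopectin-dominant grain under N limitation.

**Rate vs. supply.** With the calibrated kinetics, a day of small carbon
supply can yield $\mathrm{ISTR} > \mathrm{GCA}$ (the Michaelis–Menten
form does not know about mass balance, and no sucrose-to-starch
stoichiometric factor is specified). The literal kinetics are the
default; `starch_params(cap_rate_to_supply = TRUE)` adds the cap
$\mathrm{ISTR} \le \mathrm{GCA}$ for users who want strict per-day mass
balance.

## Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `npf0` | baseline N-to-protein conversion | – | 5.83 |
| `delta` | stress correction on `npf0` | – | 0.18 |
| `igsa0` | initial starch per grain | mg | 0.1 |
| `istr_m` | maximum per-grain starch rate | mg/day | 1.2 |
| `km` | Michaelis constant | mg | 0.7 |
| `gdd_m` | thermal time to peak amylase activity | °C d | 256 |
| `gamma` | amylase thermal-time sensitivity | 1/(°C d) | 0.002 |
| `tb, tol, toh, tm` | cardinal temperatures | °C | 7, 22, 27, 60 |
| `alpha` | amylose scaling on ln(GDD) | – | 0.4 |
| `beta` | amylose baseline correction | – | 2.1 |

The defaults are the calibrated foxtail millet values; all are exposed in
`protein_params()`, `starch_params()` and `partition_params()`. Thermal
time uses a base temperature of 10 °C (the CERES convention for millet;
the grain-quality formulation itself does not fix one), with daily
increments floored at 0 and no upper cutoff; the base is configurable
everywhere a series is built.

## The synthetic generator

`generate_scenario()` emulates, qualitatively, what a CERES-type engine
would hand the quality modules; it exists so every downstream stage is
testable without a crop-model installation or field data. Functional
forms are the simplest ones matching the expected behaviour:

* logistic aboveground biomass between `topwt_at_anthesis` (default
  6 t/ha) and `topwt_final` (12 t/ha);
* vegetative dry weight equal to the total before the remobilization
  onset day, then shedding `remobilization_fraction` (30%) of its onset
  value along a smooth half-cosine — so the grain-mass proxy
  `topwt − vwt` never decreases;
* normalized-logistic grain nitrogen to `gna_final` (80 kg/ha);
* temperature as a seasonal half-sine around `temp_mean` (22 °C) with
  seeded Gaussian noise;
* stress as piecewise-constant windows: inside a window the
  transpiration ratio is set to `water_ratio` and the plant N
  concentration is placed at `1 − n_depression` of the way up the
  minimum-to-critical ramp, so the nitrogen-stress factor equals
  `1 − n_depression` exactly; outside windows the plant sits 5% above
  the critical concentration (unstressed).

Defaults (45-day grain fill, 4×10⁵ spikes/ha × 2000 grains/spike,
remobilization onset day 21 — roughly where the default season's thermal
time crosses `gdd_m` = 256 °C d) describe a plausible irrigated millet
season; they are plausibility anchors, not reproductions of any
particular field year. What the generator does **not** emulate: weather
realism (radiation, rainfall), soil water/N feedbacks on biomass,
pre-anthesis stress memory, or cultivar differences. Tests passing on
these trajectories therefore demonstrate correctness of the quality
modules given their inputs, not skill against real field observations.
All randomness flows through one seeded, call-local RNG stream;
identical configs and seeds give byte-identical series.

`make_observations()` mirrors destructive field sampling: every
`sampling_interval` days (field practice: 7–10) plus the maturity day,
with multiplicative Gaussian noise of a chosen CV, floored at zero.

## Calibration

Calibration is staged exactly as the module structure dictates: the
protein parameters (`npf0`, `delta`) first — they are independent of the
starch module — then the five starch kinetic parameters, then the
partition pair (`alpha`, `beta`) with the starch stage held fixed. Each
stage minimizes the RMSE between simulated and observed values at the
observation days (exact day matching, no interpolation); the partition
stage minimizes the equal-weighted sum of the amylose and amylopectin
RMSEs (weights configurable; the equal split is a choice — no
combination rule is canonical).

The optimizer is a real-coded genetic algorithm: tournament selection
(size 3), BLX-0.5 blend crossover (rate 0.9) clipped to the bounds,
Gaussian mutation (rate 0.1, σ = 5% of each bound range), elitism 2,
population 50, 100 generations — conventional settings, all configurable
and seeded. Because the GA localizes but does not refine, each fit ends
with a local polish: the top three distinct individuals are refined in
box-normalized coordinates (the parameters span four orders of
magnitude) by Nelder–Mead alternated with bounded quasi-Newton
(`nlminb`) passes; the alternation copes with the kinks the
remobilization-onset branch introduces into the RMSE surface. Default
bounds bracket the calibrated values generously (`npf0` ∈ [5.0, 6.5]
spans the range reported for cereals).

A caveat the tests encode rather than hide: on smooth trajectories
`istr_m`, `km`, `gamma` and `gdd_m` can trade off — distinct parameter
sets fit the same starch curve essentially exactly. Starch-stage recovery
is therefore judged by the objective (an equivalent fit), not by
parameter distance; the protein and partition stages are identifiable
whenever the observations sample at least two distinct stress levels
(the bundled calibration fixture plants a water-stress and an
N-stress window for exactly this reason). A degenerate design with
`f(N) = 0` at every observation day makes `alpha`/`beta` unidentifiable
and is flagged with a warning.

## Numerical choices and degenerate inputs

* `tp = 0` (no transpirative demand) gives `f(W) = 1`; `f(N)` is clamped
  below at 0 so a plant below its minimum N concentration saturates
  rather than going negative.
* Day 0 carries no carbon flux or thermal-time increment; per-grain
  starch starts at `igsa0`, and the amylose ratio is defined as 0 there.
* The simulator is fully vectorized (differences, cumulative sums);
  an independent scalar day-loop recomputation agrees to 1e-9 across 100
  randomized scenarios in the test suite.
* Quality and crop-state CSVs round-trip through `write`/`read` within
  1e-9; validation reports all violations, not just the first.
* Evaluation excludes zero observations from the MRD (the relative
  difference is undefined there; anthesis-day zeros would otherwise
  poison it) with a warning, and NRMSE refuses an all-zero observation
  mean. Category boundaries (10/20/30%) belong to the higher bin.

Problem sizes throughout the tests — 35–60-day seasons, 100 randomized
scenarios for the property suites, a 50×100 GA per calibration stage —
were chosen as the smallest sizes at which the properties are
demonstrated convincingly.

## Command-line use

For scripted runs, `exec/grainqual` exposes four subcommands over the
same functions: `generate` (synthetic crop-state CSV, optionally with
sampled observations), `simulate` (crop-state CSV → quality CSV + JSON
summary), `calibrate` (staged GA fit → JSON) and `evaluate` (quality CSV
vs. observations → JSON). Runs are configured by a YAML file whose
sections mirror the parameter constructors (`scenario`, `protein`,
`starch`, `partition`, `calibration`, `io`), with flags
(`--seed`, `--out`) overriding the file and `--print-config` dumping the
resolved settings for provenance. Logs go to stderr; results never mix
into them. With fixed seeds, generate → simulate → evaluate is
byte-stable across runs.

## Known limitations

The package inherits the scope of its model: no enzyme-level mechanism
(AGPase/SSS/GBSS kinetics are folded into one activity factor), no
pre-anthesis drought memory, no protein–starch interaction, no carbon
pool carry-over between days, and no grain protein *concentration* (only
accumulation, kg/ha). Skill against real field data depends entirely on
the quality of the driving trajectories; the synthetic generator is a
test harness, not a crop model.
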