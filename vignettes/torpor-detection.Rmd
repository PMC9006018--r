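---
title: "Detecting nocturnal daily torpor from nest temperature and whole-nest respirometry"
author: "torpr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nocturnal daily torpor from nest temperature and whole-nest respirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torpr)
library(dplyr)
```

## The measurement problem

Daily torpor — a controlled, reversible reduction of resting metabolic
rate (MR), usually with a body-temperature drop, lasting less than 24 h —
is difficult to document in free-living birds without capture. For
families that rest together in a nest, two non-invasive proxies carry the
signal:

* **Nest temperature** (`T_nest`), from a logger embedded in the nest
  wall, referenced against ambient temperature (`T_a`) measured nearby.
  Resting occupants hold the nest several degrees above ambient; when the
  group lowers its metabolic rate, the elevation decays. A *substantial
  drop* is defined by the criterion `T_nest − T_a ≤ 7 °C`, and its shape
  must resemble a torpor cycle: gradual entry, a cold plateau, and active
  rewarming before dawn.
* **Whole-nest oxygen consumption** (`V̇O₂`), from an open-flow
  respirometry nest-box. The reference resting rate `MR_ref` is the
  (smoothed) value half an hour after the arrival-triggered `V̇O₂` peak;
  `MR_min` is the nocturnal minimum; the night's relative reduction is
  `(MR_ref − MR_min) × 100 / MR_ref`. A reduction of roughly ≥ 50 %,
  accompanied by a substantial `T_nest` drop, is the conservative
  guideline for a whole-group torpor night.

All quantities describe the pooled nest occupancy — a family of up to six
birds — never an individual. A shallow group-level reduction can mask deep
torpor in a subset of the occupants, so event counts derived this way are
conservative.

## The synthetic-data generator

Because the detectors make quantitative claims (sensitivity, error of the
recovered reduction, timing), the package ships a generator
([`sim_config()`], [`simulate_season()`]) whose defaults *are* the study
conditions the detectors target, and whose ground truth is known exactly.

**Ambient forcing.** A diel sinusoid (minimum near sunrise, maximum
mid-afternoon) with semi-amplitude 1.5 °C around an 18 °C mean — a damped
cycle, appropriate for nests inside a thermally massive enclosure — plus
Gaussian sample noise (SD 0.3 °C) and day-mean offsets drawn from a
warm/cold mixture (cold days with probability 0.2, shifted −6 °C). The
offsets are anchored at local noon and interpolated linearly, so a cold
front arrives over hours, not as a midnight step.

**Metabolic profile.** Whole-nest resting `V̇O₂` is 4 ml O₂ min⁻¹ (a
plausible whole-family figure for ~50–240 g of birds at thermoneutral
rest); nestlings alone hold 75 % of it by day. Adults arrive 20 min
before sunset (they return before dark), producing a spike of 2× resting
that decays with a 6-min time constant — back at the plateau well inside
30 min, so the reference value read at peak + 30 min is clean. On torpor
nights an exponential entry ramp (time constant 30 min) starts 19 min
after sunset towards `resting × (1 − torpid_fraction)` with
`torpid_fraction = 0.56`, and an exponential arousal ramp (time constant
20 min, completion defined as five time constants) finishes 45 min before
sunrise. Gas traces carry additive Gaussian noise with SD 0.2 ml O₂ min⁻¹
(5 % of resting).

**Nest thermal model.** The nest wall integrates
`T[k+1] = T[k] + Δt (−λ (T[k] − T_a[k]) + γ · MR[k])` with
`λ = 0.02 min⁻¹` (50-min time constant) and `γ = 0.06 °C min⁻¹ per
ml O₂ min⁻¹`, giving equilibrium elevations of `γ·MR/λ` = 12 °C at night,
9 °C by day, and 5.3 °C during a 56 %-deep torpor plateau — the torpid
nest sits below the 7 °C criterion, the attended nest above it. The
recurrence is linear, solved exactly with a recursive filter; for constant
forcing the fixed point `T_a + γ·MR/λ` is reproduced to numerical
precision, and a 1-second brute-force integrator agrees on criterion
crossing times to within one sample. Logger behaviour is emulated with
Gaussian accuracy noise (SD 0.2 °C) and quantization to 0.0625 °C steps.

Two emergent properties matter. First, the nest's thermal inertia makes
`T_nest` peak *after* the metabolic decline has begun (the nest is still
warming from the adults' arrival), so the detected `T_nest` decline lags
the `V̇O₂` onset by tens of minutes — the generator reproduces this lag
without it being scripted. Second, because nestlings keep the nest ~9 °C
above ambient all day, a detected drop is always a genuine downward
crossing of the criterion, and the morning departure of the adults (a
12 → 9 °C elevation change) never creates one.

**Randomness.** All draws flow from one root seed through a documented
substream derivation (`substream_seed(root, nest, night)`), so any single
nest-night can be re-simulated in isolation and season files are
byte-identical across runs with the same config.

**Torpor incidence.** Torpor is drawn per nest-night with probability
0.03. A logistic coupling of that probability to the day-mean ambient
offset is available (`ta_coupling_slope`) but defaults to off: the field
data establish an association between cold days and torpor nights, not a
functional form, so the package does not presume one. The day-level
contrast is instead replicated with `simulate_day_records()`, which takes
the two group means as generative settings.

**What the generator does not emulate.** Individual-level heterogeneity
(mixtures of torpid and normothermic birds in one nest), huddling
geometry, mass-specific allometry, incubation rhythms, logger dropouts
and clock drift, and weather-driven MR variation. Passing tests therefore
demonstrate that the detectors recover the *assumed* physiology under
realistic noise — not that real colonies behave like the model.

## Detection conventions and numerical choices

**Drop events** ([`detect_drops()`]). The criterion is a pointwise
inequality; to make it operational the implementation adds:

* minimum below-criterion persistence 30 min (6 samples at 5-min logging
  — single-sample crossings are unreliable at ±0.5 °C logger accuracy);
* runs separated by < 30 min are merged; one event per nest-night after
  deduplication (the deepest is kept);
* a *downward crossing* requirement: the run must be entered from above
  the criterion. Without it, every vacant nest (elevation ≈ 0) would be
  one endless "event";
* optional restriction to crossings inside the sunset-to-sunrise window,
  used by all nocturnal statistics (nights are attributed to the calendar
  date of their sunset);
* "decreased continuously" is evaluated on a 15-min running median with a
  0.25 °C per-step tolerance (raw 0.0625 °C quantization breaks strict
  monotonicity). The event start is the *trailing* edge of the
  pre-decline plateau — the last sample still within tolerance of the
  local maximum — which is the time from which the trace decreases
  continuously;
* event end: first return of the smoothed trace to within 2 °C of its
  start value, or first return of the smoothed elevation above
  `criterion + 2 °C` (an arousal restores the elevation even when a cold
  snap keeps absolute temperature low), searched up to 12 h past the run
  (cold spells can defer absolute recovery for days); gaps > 30 min flag
  the event and exclude it from duration statistics.

**Shape score** ([`shape_score()`]). The field criterion was validated
against video in the original study; the quantitative rule is not public,
so the template here is the package's own, documented design: the mean of
an entry sub-score (fraction of non-increasing smoothed steps over the
cooling ramp, rescaled above the 50 % chance level, zero if the ramp is
shorter than an hour), a plateau sub-score (fraction of below-criterion
samples within 2 °C of the event minimum), and a rewarming sub-score
(rewarming at least half as fast as cooling, gated on the trailing
elevation returning above `criterion + 1`). Events below 0.5 are rejected
as artefacts. Noise wandering at the criterion is rejected on ≥ 95 % of
simulated artefact nights; noise-free simulated torpor cycles score
≥ 0.9; a step drop with instant recovery scores 2/3 (no entry ramp) and
is retained; departure cooling without rewarming scores ≤ 1/3 and is
rejected.

**Occupancy** ([`infer_occupancy()`], [`select_monitored_nests()`]). A
night is occupied when mean nocturnal elevation exceeds 3 °C (the
generator's occupied nests sit at 12 °C, empty ones at 0) or a drop event
spans it; nights with under 50 % sample coverage are unknown and leave
all denominators. A nest enters the season table when its longest run of
*consecutive* occupied nights reaches 30; "observations" is the sum of
occupied nights over selected nests, matching the published table's
"no. nests × nights" column.

**Night scoring** ([`score_night()`]). `MR_ref` is read from a 15-min
moving average at exactly peak + 30 min: the point value the definition
names would inherit the sensor noise of a single sample. The nocturnal
minimum uses a wider 30-min window, because the minimum of a noisy series
carries a downward extreme-value bias that shrinks with the averaging
window; with the default noise this keeps the reduction's mean absolute
error under 2 percentage points. Onset is the first time the smoothed
trace stays below `0.9 × MR_ref` for 30 min, tracked back to the local
start of the decline; arousal end is the first recovery above the same
threshold after the minimum (trace end, flagged, if never). These onset
and end conventions are the implementation's — the field study reports
bout times without defining them — and the 0.9 factor is exposed so its
sensitivity can be examined. On a flat night the measured reduction is
not zero but the noise envelope of the minimum statistic (~10–15 % under
default noise); the reduction's ground-truth comparison is therefore
meaningful only for nights with a generative torpor depth.

**Classification** ([`classify_torpor()`]). Torpor requires
`reduction ≥ 50 %` (the boundary counts) *and* a linked drop event where
temperature data exist; nights without temperature coverage are
classified MR-only and flagged. A `"replication"` preset lowers the
threshold to 48 %, since under the "approximately 50 %" reading a 49 %
night still qualifies.

**Sun times** ([`sun_times()`]). NOAA solar-position computation with
rise/set at solar altitude −0.833° (standard refraction plus solar
radius; exposed as a parameter, since the original timing statistics do
not state their convention). Polar latitudes are rejected explicitly.
Agreement with an independent implementation of the NOAA equations is
well within ±2 min across the season; all instants are UTC.

**Aggregation** ([`pool_seasons()`], [`describe_events()`]). Totals are
exact integer sums. Percentages round half-up — nights to one decimal,
nests to integers — which is the printed precision of the published
season table; base R's round-half-even would differ at exactly .5.
Across-season statistics use the sample SD. Whether "observations"
counts all nights or occupied nights only is ambiguous in the source
table; the implementation counts occupied nights with at least 50 %
coverage.

**Mixed-model contrast** ([`contrast_ambient()`]). Day-level ambient
records (labelled by the torpor status of the *following* night) are fit
with `lme4`/`lmerTest` as `response ~ group + (1|year) + (1|nest)`;
group means and 95 % Wald/Satterthwaite CIs come from `emmeans`, the
p-value from the Satterthwaite test of the group term, and the marginal
R² is Nakagawa's (fixed-effect variance over total modelled variance).
The CI type of the original table is unstated; 95 % is assumed. Identity
checks guard the degenerate cases: when random-effect variances collapse
to zero (including one observation per nest, where nest and residual
variance are unidentifiable but fixed effects are not), the point
estimates equal the ordinary two-group linear model. No multiple-testing
correction is applied, matching the original analysis.

## Validation summary

The test suite validates, among others (problem sizes chosen to keep the
default run under a minute per file):

* exact reproduction of the published season-table arithmetic (16 673
  observations / 423 drop-nights pooled over 2010–2015; 70 ± 20 % of
  nests with a drop; the 2013 row's 5.9 % and 100 %);
* segmentation equal to an independent quadratic run-length oracle on
  200 random traces; alignment equal to a quadratic nearest-neighbour
  scan; Pearson r/p equal to the textbook formulas at 1e-12;
* 100 % sensitivity and specificity of drop detection on simulated
  seasons (noisy and noise-free) whose torpor plateaus sit below the
  criterion for at least 2 h;
* reduction recovered with MAE < 3 points and classification accuracy
  ≥ 95 % on 100 noisy nights; positive thermal lag on ≥ 95 % of 100
  noise-free nights; drop magnitude within 1 °C of the clean-trace
  ground truth;
* ≥ 90 % CI coverage of both generative group means over 500 replicates
  of the day-level contrast at n = 60 (6 torpor / 54 non-torpor days,
  generative means 17.3 / 20.8 °C, residual SD 2.9 °C).

## Limitations

The two signals are group-level; per-individual torpor cannot be
attributed. The shape template and the onset/arousal thresholds are
package conventions, not field-validated rules, and should be treated as
tunable when applied to data from other systems. Event durations depend
on the recovery convention (the original study reports durations without
defining event end). The generator's cold-day mechanism is a mixture
model of convenience; it produces cold spells but not weather. Gaps are
never interpolated on read, and the detectors' gap policies (flagging,
coverage thresholds) are deliberately conservative.
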