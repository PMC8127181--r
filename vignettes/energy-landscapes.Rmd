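---
title: "Methods: from biologging traces to an energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biologging traces to an energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energyscape)
```

## The model and its assumptions

`energyscape` maps the energetic balance of a central-place diving
forager onto the bathymetry around its colony. The landscape value of a
marine grid cell is the total relative cost

$$\mathrm{TRC} = \mathrm{TCF} / \mathrm{TBT} \quad
  [\mathrm{J\,kg^{-1}\,s^{-1}}],$$

the mass-specific total cost of a foraging trip to that cell (diving
plus commuting) divided by the total bottom time the trip would yield
there. Bottom time stands in for energy gain: across several penguin
species most prey captures happen during the bottom phase of dives, so a
cell where a trip buys more bottom time per joule is a better cell. The
model's core assumptions are:

1. **ODBA is a linear proxy for metabolic power.** Overall Dynamic Body
   Acceleration — the summed absolute dynamic accelerations after
   removing the static (gravitational) component with a 1 s moving
   average — converts to oxygen consumption linearly,
   $\dot V_o = a + b\,\mathrm{ODBA}$, with allometric constants
   $a = 2.75\,BM^{0.73}$, $b = 3.52\,BM^{0.94}$ (ml O₂ min⁻¹, body mass
   in kg), and 1 ml O₂ min⁻¹ ≈ 0.333 J s⁻¹ (from ~20 kJ per litre of
   oxygen).
2. **Dive cost depends on target depth, differently for benthic and
   pelagic dives.** Per class, the per-dive ODBA sum is regressed on
   maximum dive depth, and bottom time on maximum dive depth. The
   benthic/pelagic split is structural: a dive is benthic when its
   maximum depth lies within ±10 % of the previous dive's maximum (the
   intra-depth-zone rule), because serial same-depth dives indicate
   seabed foraging.
3. **A trip to a cell is a bundle of MND dives spanning a depth
   gradient.** Birds deepen their dives on the way out, so the power per
   benthic dive is averaged between the value at 3 m (the minimum depth
   counted as a dive) and at the cell's seabed depth — a trapezoidal
   mean — and likewise the benthic bottom time is averaged between the
   minimum observed value (mBBT) and the value predicted at the cell's
   depth. Pelagic dives are evaluated at the median pelagic depth, a
   constant per run, because the pelagic depth distribution is strongly
   left-shifted (hence a median, not a mean).
4. **Commuting is straight-line swimming.** Travel cost is distance /
   swim speed × mass-specific transport cost, doubled for the return.

One printed form of the trip-cost equation can be read two ways: the
dive-cost expression "(MP(3 m) + MP) × MND / 2" is taken here as
*trapezoidal mean × dive count* — i.e. DD × (MP(3 m) + MP)/2 × MND × p —
which matches the accompanying prose ("a mean is calculated and the mean
multiplied per MND"). The same reading is applied to bottom times in
TBT. This is a deliberate interpretation, recorded here rather than made
silently.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| dive acceptance threshold | 3 (strict >) | m | avoids surface-zone pressure noise |
| surface reference | 1 | m | hysteresis band for dive start/end with cm-level sensors |
| ODBA smoothing window | 1 | s | separates stroking dynamics from posture/gravity |
| IDZ band | ±10 % | – | serial-depth criterion for benthic dives |
| first dive of a trip | pelagic | – | no predecessor; conservative, configurable |
| bottom-phase speed threshold | 0.25 over ≥ 5 s runs | m s⁻¹ | standard time-depth-recorder practice; the phase wording ("steady increase/decrease") is qualitative |
| colony radius for trip splitting | 200 | m | operationalises "departed from the colony" |
| swim speed | 2.3 | m s⁻¹ | measured commuting speed for gentoos |
| transport cost | 16.1 | W kg⁻¹ | swim-canal / at-sea minimum cost of transport |
| body mass | 5.2 (gentoo), 3.7 (chinstrap) | kg | sets the allometric V̇o constants |
| IDW power / neighbourhood | 2 / all samples | – | canonical Shepard form; recorded in landscape metadata |
| MND mode | fixed median | – | `"distance"` switches to the dives-vs-max-distance regression for populations whose trip effort scales with range |
| DD statistic | median | s | per-class dive duration; a mean is available via the trip tables if preferred |

mBBT (minimum benthic bottom time) is always **derived from the
processed dive table**, never supplied as a constant: published tables
of this quantity are easy to mistranscribe, and it is cheap to recompute
from data.

ODBA sums are kept in *g-sample* units at the native sampling rate, with
the rate recorded on the `OdbaSeries`. No published unit convention
exists for "sum of ODBA"; what matters is that the calibration
regressions and the V̇o conversion are applied to the same quantity, and
keeping the raw sum makes that internal consistency explicit.

## The synthetic generator: what it emulates, what it does not

`syntheticConfig()` + `simulateDeployment()` produce a colony of
deployments with *known ground truth*: per-dive class labels, depths,
bottom times and target ODBA sums, plus the true ODBA–depth and bottom
time–depth laws. Design choices:

- **Trips** are petal-shaped loops at constant ground speed whose
  cumulative length matches the configured scale (default 20 km, within
  the observed range of chick-guard trips), with 5-min fixes and small
  GPS jitter; first and last fixes sit at the colony.
- **Dives** are trapezoids: constant-rate descent/ascent (1.5 m s⁻¹) and
  a flat plateau whose duration follows the class's true bottom-time law
  plus multiplicative noise, quantised to the 1 Hz depth grid. Benthic
  dives touch the (bilinearly interpolated) seabed at the dive's
  position; class labels are generated *first* as serial bouts steered
  toward the target benthic fraction, and pelagic depths are drawn
  log-normally (median 15 m) with rejection out of the preceding dive's
  intra-depth zone — so the generator's labels remain recoverable by the
  IDZ classifier even though IDZ is itself a heuristic.
- **Acceleration** is a fixed 1 g gravity vector (an optional slow
  rotation exercises posture change) plus a square-wave stroking signal
  whose 0.2 s period divides the smoothing window. Each dive's amplitude
  is calibrated through a unit-amplitude ODBA pass: because ODBA is
  exactly linear in the dynamic amplitude, the per-dive ODBA sum
  recovered downstream equals the configured law value *exactly* when
  noise is zero. This is what makes noiseless end-to-end recovery a
  meaningful machine-precision test rather than a loose simulation
  check.
- The default true laws (benthic ODBA sum $2.5\,z^{1.05}$, pelagic
  $20 + 4z$; bottom times $80 - 0.15z$ and $45 - 0.3z$ s; 10 %
  multiplicative noise) were chosen once to give fitted R² near the
  0.70–0.78 range reported for real deployments and landscape values of
  order 10² J kg⁻¹ s⁻¹.

The generator does **not** emulate: behaviourally realistic movement
(no correlated random walks or state switching), currents or tides,
clock drift between channels, sensor spikes/dropouts, or body-pitch
dynamics. Passing tests therefore demonstrate that the *pipeline*
recovers known structure from data of the right shape and sampling; they
do not validate the biological assumptions (ODBA linearity, bottom time
as gain) on real animals.

## Numerical choices

- **Smoothing** is a centred moving average (symmetric phase response);
  even window lengths put the extra sample on the trailing side; edges
  use shrunken windows, and traces shorter than the window fall back to
  the whole-trace mean.
- **Regression fitting** is least squares on the untransformed response
  for every family (power and exponential-rise via Levenberg–Marquardt,
  started from a log–log fit and from the response maximum
  respectively), so the R² used for family selection is comparable
  across families on the original scale. Ties within 1e-9 go to the
  family with fewer parameters, then to registry order — selection is
  deterministic. A constant response yields a flat linear fit with
  R² = 0 rather than an error. Predictions are floored at physical
  bounds (0; 1 for dive counts) and warn beyond [min, 1.25 × max] of the
  training predictor: landscape cells routinely exceed the deepest
  observed dive, and the extrapolation is deliberate but loud.
- **Bottom phases**: descent/ascent runs need ≥ 5 consecutive
  above-threshold vertical speeds, which keeps centimetre-level plateau
  noise from fragmenting the phase; V-shaped dives get bottom time 0.
- **Distances** are haversine on a 6371.0 km sphere everywhere —
  trip lengths, dive georeferencing, grid distances, IDW weights —
  ellipsoidal refinement is irrelevant at foraging-trip scales.
- **IDW** returns the sample value exactly when a target coincides with
  a sample (within 1 mm), so interpolating onto the cell centres
  reproduces the cell values; the convex-combination bound (raster
  extrema never exceed sample extrema) is asserted on every build.
- **Medians** use R's midpoint-of-two convention for even n.
- **Degenerate inputs**: traces never exceeding the 3 m threshold give
  an empty dive table; trips without dives have undefined (NA) duration
  with a warning; cells shallower than 3 m or with non-positive total
  bottom time are flagged and excluded from interpolation rather than
  carried as sentinels; a class with fewer than 3 dives is a hard error
  naming the class.
- **Reproducibility**: every generator operation derives a child seed
  from the configuration seed and the individual id, so objects are
  byte-identical across runs and call orders (R's default
  Mersenne–Twister).

## Problem sizes

The shipped tests and examples use one colony of 8 individuals, ~20 km
trips (≈ 160–170 dives each at 50 Hz accelerometry), and a 100 × 100
grid of 500 m cells over a ±25 km extent — sizes chosen so a full
synthetic deployment, calibration and landscape build completes in a
couple of minutes on a single core while still exercising every stage at
realistic sampling rates. Oracle-equivalence checks run the primitives
against brute-force references on 1000 random instances each; parameter
recovery uses 50 replicates of 300 dives at 10 % noise.

## Known limitations

- Only lon/lat grids with haversine distances are currently wired
  through; projected-CRS input (polar stereographic bathymetries) must
  be converted to lon/lat cell centres first, and GeoTIFF rasters must
  be exported to xyz tables.
- The IDZ rule misclassifies the first dive of every benthic bout by
  construction (it has no same-depth predecessor); per-class regressions
  fitted from IDZ labels inherit that contamination, which is visible in
  the synthetic tests as slightly biased pelagic fits and is why
  ground-truth recovery is scored against the generator's labels.
- The landscape assumes one trip = one cell: a bird that works several
  depth zones in one trip is represented only through the class
  proportions and the trapezoidal gradient, not as a mixture of targets.
- Benthic and pelagic laws are pooled across individuals; no
  mixed-effects structure.
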