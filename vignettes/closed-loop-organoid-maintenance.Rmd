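---
title: "Closed-loop organoid maintenance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop organoid maintenance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidrig)
```

`organoidrig` is a desk-scale, hardware-free implementation of a
feedback-driven maintenance platform for organoid culture. A syringe pump
periodically exchanges culture media; the conditioned media accumulates in a
15 mL conical collection reservoir that is photographed against an LED
backlight; a computer-vision estimator converts each photograph into a
volume in microlitres; and a feedback interpreter compares that estimate
with the expected reservoir volume and issues corrective pump jobs until the
two agree. Around this loop sit a device-orchestration layer (schedules,
pause/defer, shadows, uploads) and an electrophysiology analysis that asks
whether feeding perturbs the firing of the cultured tissue. Everything the
hardware would provide is simulated, with ground truth, so the whole control
loop can be exercised end to end on one desk.

This vignette records the models the package implements, the parameters that
matter, and the choices made where the design was genuinely open. Nothing
stated here is an empirical claim beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## Volume estimation from reservoir photographs

### Quality gates

Two checks precede any estimation. *Lighting*: the per-channel mean RGB over
a designated region must each exceed 20 (of 255) — a failed backlight makes
all three collapse toward zero. *Blurriness*: the variance of the Laplacian
of the grayscale profile patch must reach 50; defocused optics smooth away
the high-frequency structure this statistic measures. Both thresholds are
configurable arguments of `check_quality()`; the pipeline entry point
`estimate_image_volume()` refuses to produce a volume for a failed image
(`status = "rejected_quality"`), so no gated image ever reaches the
calibration model.

### Meniscus detection by HSV row profiles

A narrow pixel patch down the tube's vertical axis is converted to HSV and
summed row-wise, bottom to top (`hsv_row_profiles()`). At the air–liquid
boundary the three channel profiles carry complementary signatures: the hue
profile rises abruptly, the saturation profile attains its absolute maximum
(the meniscus band is the most strongly colored structure), and the value
profile attains its absolute minimum (it is also the darkest). "Abrupt rise"
is implemented as the row maximising the one-step forward difference — the
simplest operator with that meaning, and the easiest to test. The boundary
row is the arithmetic mean of the three channel rows, rounded with ties
falling toward the tube bottom: under-estimating the boundary over-segments,
which the meniscus refinement step corrects, whereas over-estimating loses
fluid rows outright.

Flat profiles (no extremum above the `noise_floor` argument) raise a
boundary-not-found condition; `measure_pixel_area()` interprets that as an
empty tube (pixel area 0), which is the correct reading for a freshly
swapped reservoir.

### Segmentation and the pixel-area convention

`segment_fluid()` marks every ROI pixel strictly below the boundary row as
fluid — a *fill-level rectangle* — then adds pixels within ±30 rows of the
boundary whose HSV values fall inside configurable meniscus bounds. The
pixel area is therefore a monotone proxy for fill height rather than a
literal cross-section of the fluid silhouette; the calibration polynomial
absorbs the geometry. The simulated renderer records its ground-truth pixel
count in the same convention, which is what makes "segmented area within 2%
of truth" a well-posed statement. The default meniscus HSV bounds were
chosen against rendered fixtures; on real imagery they are expected to need
re-tuning, which is why they are plain arguments.

### The piecewise cubic calibration

Volume is mapped from pixel area `x` by two cubics, one per tube geometry:

$$
V(x) =
\begin{cases}
5.09\times10^{-9}x^3 + 2.39\times10^{-5}x^2 + 0.13x - 1.28 & x < 4446 \\
2.60\times10^{-11}x^3 + 5.38\times10^{-7}x^2 + 0.62x - 1288.37 & x \ge 4446
\end{cases}
$$

with output in microlitres: the conical tube bottom (volumes under 1.5 mL)
and the cylindrical body follow different area–volume laws, and fitting them
separately keeps each branch near-exact. `reference_calibration()` carries
these published constants; `fit_calibration()` reproduces the procedure on
any `(pixel_area, volume_ul)` dataset, assigning entries to branches by a
1500 µL breakpoint volume and locating the pixel-area breakpoint as the root
of the conical fit at that volume. The two printed branches differ by about
15 µL where they meet — within the model's own error scale — so
`estimate_volume()` is monotone within each branch with a single bounded
step at the breakpoint. Negative polynomial output (the conical branch's
constant is −1.28) is clamped to 0 µL: volumes cannot be negative.

Degree 3 per branch is fixed by default (matching the reference model) but
overridable. Fitting requires at least 8 entries per branch — a cubic has
four coefficients, and anything less is barely constrained.

### Validation

`loo_metrics()` implements leave-one-out cross-validation: every entry is
predicted by a model refit on the others. Errors are reported in µL and as
percentages under two documented denominators — percent of the entry's true
volume (zero-volume entries excluded) and percent of the 12 mL full scale —
because a bare "%" is ambiguous for a quantity spanning two orders of
magnitude. R² is reported per branch. The package's acceptance run uses 60
rendered images with ±1 % multiplicative area noise; the resulting MAE
(tens of µL, a few tenths of a percent of full scale, R² > 0.99 per branch)
sits on the same scale as the platform the package models, but it is a
property of the synthetic renderer, not a reproduction of any photographic
dataset.

## The feedback interpreter

The expectation ledger carries the reservoir volume implied by the sum of
*scheduled* pump actions. Each estimate is classified, in order:

| category | rule (study values) |
|---|---|
| tube change | previous estimate − estimate ≥ 2000 µL **and** estimate < 2000 µL |
| anomaly | estimate − expectation ≥ 2000 µL |
| within tolerance | \|estimate − expectation\| ≤ 143 µL |
| under / over volume | otherwise, by sign |

Out-of-tolerance estimates trigger 1-indexed feedback iterations: under
volume, iterations 1–5 send one aspiration matching the discrepancy;
iterations 6–19 send 1000 µL pulls at 10× syringe speed (the force needed to
break through resistance in protein-rich conditioned media); iteration 20
requests manual intervention and suspends all pump actions. Over volume,
dispenses are capped at 200 µL per action and two dispense-bearing
iterations per trigger — dispensing is the dangerous direction (well
overflow) — after which the loop alerts and halts, symmetric with the
under-volume terminal state. An anomaly alerts and halts immediately. A tube
change resets the expectation to the current estimate rather than zero, so
residual media in a swapped tube is tolerated.

Three open points were resolved as follows:

* **Corrective jobs do not move the expectation.** If feedback aspirations
  raised the expected volume by their own commanded volume, the target would
  recede from the very correction chasing it, and the documented behavior —
  a pull raising the estimate *above* a fixed expectation, then dispenses
  settling back into tolerance — would be unreachable. Scheduled jobs alone
  carry expectation deltas; feedback jobs are logged with delta 0.
* **Pull escalation** reads "increasing by one" as the *count* of pulls per
  iteration (iteration 6 sends one, 7 sends two, …). The single-pull
  reading is selectable via `pull_escalation = "single"`; both agree with
  the single-pull-at-iteration-6 trace the escalation is anchored to.
* **The 2 mL safety cap is counted against measured perfusion** — the sum of
  absolute estimate changes across a trigger's feedback iterations, reset on
  success — not against commanded volume. Commanded pulls are 1000 µL each,
  so a commanded-volume reading would halt the loop at iteration 7 and make
  the documented pull phase (iterations 6–19) unreachable; measured
  perfusion is also the quantity the cap exists to bound (fluid actually
  moved into the reservoir). The companion retry bound (20) coincides with
  the alert iteration.

Dispense feedback is well-directed (fresh media to the culture well, which
is the side that lost fluid to an over-aspiration) and leaves the reservoir
expectation unchanged.

## The rig simulator

`rig_state()` tracks chamber, reservoir and tubing volumes. The chamber's
ideal operating range is 350–700 µL; aspiration stops drawing fluid at the
170 µL floor (air instead), and dispensing beyond the 1500 µL overflow catch
latches an overflow state that refuses further jobs. Volume is conserved
exactly: chamber + reservoir − cumulative dispensed is constant, and a
property test holds this to 1e−9 µL over arbitrary job sequences.

The fault model is this package's invention — the platform it models reports
clogging as a failure mode, not its statistics. A clog arises per
aspiration-type action with probability `clog_prob` and persists; while
clogged, each aspiration retains a Beta(2, 2)-distributed fraction of its
commanded volume; clogs clear spontaneously with probability 0.3 per action
and with probability 0.8 on a pull. Defaults were chosen so that a run with
`clog_prob = 0.3` produces feedback-event counts of the same order as the
platform's two documented 7-day runs (tens of corrective actions over 28
feeds); they are order-of-magnitude calibrations, not fitted quantities.

The renderer draws the backlit tube from its geometry — a cone holding the
first 1.5 mL (apex down) under a cylinder of radius 7.45 mm, 1 µL = 1 mm³ —
at 6 px/mm, with a 3-row meniscus band at the interface. Colors are
synthetic HSV triples chosen so the channel profiles carry the signatures
the detector looks for (teal fluid, dark saturated meniscus, bright warm
backlight); the backlight keeps saturation 0.15 so its hue is stable under
noise, as a tinted LED panel's would be. Per-pixel Gaussian noise
(sd 4/255 by default, on the order of a small camera sensor in a dark
refrigerator), box-blur passes and a lighting scale provide controllable
defects. Ground truth (central meniscus row and fill-level pixel count) is
returned with every render. What the renderer does *not* model: refraction
through the tube wall, graduation marks and printed text, reflections,
perspective, and real media color — so passing round-trip tests demonstrate
the pipeline's internal consistency and noise robustness, not performance on
photographs.

`run_experiment()` closes the loop: a calibration is fitted once from
noise-free renders (40 volumes spanning both branches), then each scheduled
feed cycle runs aspirate-dispense on the simulated rig, images the
reservoir, estimates, classifies and corrects. Simulated scenarios place a
reservoir swap after feed 16 (about day 4 of a 7-day run) so that the
expected volume at the swap (≈2.3 mL) exceeds the 2 mL drop threshold and
the tube-change signature is unambiguous; a swap much earlier would sit at
or below the printed rule's boundary.

## Orchestration

The in-process broker implements the publish/subscribe contract with MQTT
topic semantics (`+` one level, `#` trailing remainder), at-least-once
delivery to matching subscriptions, and device-side command-set enforcement:
a device executes only its declared commands and logs anything else as
rejected. No test requires a network; an external MQTT-compatible broker can
stand behind the same surface.

`simulate_devices()` is a deterministic chronological scheduler under
simulated time (a 7-day schedule runs in milliseconds). Pause semantics are
cooperative and job-atomic: an exclusive device (the recording unit) waits
for every device to go idle — a running feed completes — and blocks all
other job starts for its duration; queued jobs re-run afterwards and are
flagged `deferred`. Priorities default to recording > feeding > imaging >
uploading and are configurable. Every transition appends a device-shadow
row, so the shadow always reflects the new state before the next job starts.
Every submission terminates as done, failed or rejected — no job is lost —
and a randomized-schedule property test asserts exactly that, along with
recording exclusivity.

Experiment metadata lives in `metadata.json` under the experiment UUID
(collisions refused), with raw and analyzed files indexed under distinct
sub-keys and an append-only index. The upload queue marks a file uploaded
only after its stored MD5 matches the local one, retries on mismatch, and
alerts after a bounded number of retries.

## The feed-effect statistic

For every recording, a 90-s window slides in 1-s steps (half-open
`[t, t+90)`; boundary spikes count left) and the mean firing rate per unit
is computed per window: `floor((duration − 90)/1) + 1` windows in all. Each
unit's window rate *a* is contrast-normalized against that unit's mean
window rate *m*:

$$\|x\| = \frac{a - m}{a + m} \in [-1, 1],$$

so 0 means the unit fired at its own average, ±1/3 means roughly double or
half of it, and −1 a silent window; a fully silent unit (0/0) is defined as
0. For every window position, the mean and standard deviation of these norms
are pooled over *all units of all no-feed recordings*, and each feed
recording is z-scored against that per-window baseline,
`z = (‖x‖ − μ)/σ`, then averaged over all units of all recordings sharing a
feed volume (150/300/600/900 µL conditions). Recordings of unequal duration
are aligned by truncation to the shortest common window axis; windows with
zero baseline σ yield flagged NAs.

The synthetic cohort generator draws per-unit base rates log-normally
(median ≈ 1.7 Hz, mean ≈ 2 Hz, sdlog 0.6 — the scale of spike-sorted unit
yields in cortical organoid recordings), fires each unit as a Poisson
process over a 15-min recording, and optionally multiplies rates by a factor
for a fixed interval from feed onset (minute 5). Defaults (40 units per
recording, 28 no-feed and 4 × 3 feed recordings) mirror the study design the
statistic comes from. What the generator does not emulate: population
bursts, rate autocorrelation, unit appearance/disappearance, and
non-stationarity — so the null calibration shown by the tests (condition
averages within ±0.7 baseline SD) demonstrates the statistic's behavior
under independent Poisson variability, not under real network dynamics.
`recording_summaries()` supplies the descriptive companions: unit count,
median per-unit rate, and the population rate in 100 ms bins divided by unit
count.

## Electrode-grid alignment

The HD-MEA grid is 220 × 120 = 26,400 electrodes at 17.5 µm pitch (7.5 µm
pads) over a 3.85 × 2.1 mm sensing area. `build_mapping()` solves the 3 × 3
projective transform exactly from four point correspondences (image pixels →
grid corners in mm, derived from the corner anchor and electrode geometry).
`contact_map()` marks an electrode when the organoid mask's contour
(foreground pixels with a 4-adjacent background neighbour, frame edges
included) enters its *pitch-sized Voronoi cell* rather than its 7.5 µm pad:
the cells tile the sensing area, so a continuous contour always marks a
connected path of electrodes, which the sparse pads would not guarantee.
Masks are expected at roughly half-pitch resolution (default 10 µm/px);
much finer masks mark slightly more cells (every cell the continuous curve
clips), much coarser ones fewer. Overlay coordinates are emitted on the
electrode axes; the axis extent defaults to the grid-derived 3850 × 2100 µm,
with `axis_extent_um` available to reproduce plots that use other axis
conventions (one published convention reads x = 3580, which conflicts with
the 3.85 mm sensing width and is treated here as an override, not the
default).

## Numerical choices, sizes and limitations

* Image rows are 1-based from the top in all R structures; profiles run
  bottom-to-top; the conversion lives in `hsv_row_profiles()` and nowhere
  else.
* Boundary-row ties round toward the tube bottom (`floor(x + 0.5)` on row
  numbers).
* The breakpoint root is bracketed near the conical branch's own area range
  before `uniroot` — a cubic trusted far outside its data can bend back and
  lose the root.
* Simulated runs use event-driven time (no fixed tick); closed-loop tests
  use 28 feeds at 6-h periods, calibration tests 40–60 rendered images, and
  the feed-effect tests 40 recordings of 40 units — sizes chosen so the
  whole suite exercises every path in well under a minute of compute while
  keeping every statistic far from its decision boundary.
* All stochastic tests fix their seeds; the acceptance script derives all of
  its seeds from `--seed`.
* Known limitations: PNG is the only photographic input format wired in;
  raster exchange is CSV (one spike per row) rather than a binary
  container; the MQTT adapter is a documented contract, not a network
  client; and all accuracy statements are statements about the synthetic
  renderer and generator, by design.
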