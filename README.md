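# organoidrig

Closed-loop organoid maintenance on a desk: computer-vision fluid-volume
estimation, a volumetric feedback interpreter, device orchestration, a
simulated microfluidic rig with ground truth, and the feed-effect
spike-train statistic.

## The problem

Long-term organoid culture needs media exchanged every few hours, around the
clock, without removing samples from the incubator. An automated platform
does this with a syringe pump; the aspirated conditioned media collects in a
15 mL conical reservoir that a camera photographs against an LED backlight.
Conditioned media clogs microfluidic lines, so every pump action is verified
by *vision*: the photograph is converted to a volume estimate, compared with
the volume the pump's job history implies, and corrective jobs (aspirate,
high-speed "pull", dispense) are issued until the two agree — or a human is
alerted. The companion scientific question is whether all this plumbing
perturbs the tissue: spike rasters recorded during feeds are reduced to a
normalized, baseline-z-scored firing-rate trace per feed-volume condition.

`organoidrig` implements the whole loop hardware-free, for people who want
to study, test, or extend the control logic and the analysis: the vision
estimator and its calibration, the feedback state machine, the
orchestration semantics, a fluid-physics rig simulator with a reservoir
image renderer (known ground truth), and the electrophysiology statistic
with a synthetic cohort generator.

## The models at the core

**Volume estimation.** A patch down the tube's axis is converted to HSV and
summed row-wise; the meniscus row is the mean of the hue profile's sharpest
rise, the saturation maximum and the value minimum. Pixels below the
boundary (plus HSV-matched meniscus pixels) form the segmented area `x`,
mapped to microlitres by a piecewise cubic with branches for the conical and
cylindrical tube sections:

    V(x) = 5.09e-9 x^3 + 2.39e-5 x^2 + 0.13 x - 1.28        x < 4446 px
           2.60e-11 x^3 + 5.38e-7 x^2 + 0.62 x - 1288.37    x >= 4446 px

`fit_calibration()` reproduces the procedure on any (area, volume) table;
`loo_metrics()` quantifies it by leave-one-out cross-validation.

**Feedback.** Estimates are classified against the expectation ledger
(tolerance ±143 µL): within tolerance / under volume / over volume /
anomaly (≥ 2000 µL above expectation) / tube change (≥ 2000 µL drop to a
level < 2000 µL). Under-volume corrections escalate: difference-matched
aspirations (iterations 1–5), 1000 µL pulls at 10× speed (6–19), then a
manual-intervention alert with a halt (20). Dispenses are capped at 200 µL
and two iterations.

**Feed effect.** Per 90-s sliding window (1-s steps), each unit's rate `a`
is contrast-normalized against its own mean `m` as `(a−m)/(a+m)`; per-window
baselines pooled over all units of all no-feed recordings z-score the feed
recordings, averaged per feed-volume condition.

## Worked example

Calibrate from rendered reservoir images, validate, and estimate:

```r
library(organoidrig)
set.seed(7)
cfg  <- render_config()
vols <- c(seq(60, 1400, length.out = 20), seq(1600, 12000, length.out = 40))
ds   <- render_calibration_dataset(vols, cfg, area_noise = 0.01)
model <- fit_calibration(ds, breakpoint_volume = 1500)

loo_metrics(ds)
#> Leave-one-out validation over 60 entries
#>   MAE  45.7 uL (2.07% of true volume, 0.38% of full scale)
#>   RMSE 62.1 uL (0.52% of full scale); error SD 62.6 uL
#>   R2: conical 0.9969, cylindrical 0.9994

r <- render_reservoir(5000, cfg)           # a 5 mL reservoir, with noise
estimate_image_volume(r$image, model)
#> <volume_estimate: 5002 uL from 24564 px>
```

The mean absolute LOO error is 45.7 µL — about 0.4 % of the 12 mL full
scale — and the 5 mL render reads back as 5002 µL. Then close the loop on a
simulated 7-day run with a line that clogs on 30 % of aspirations:

```r
ex <- run_experiment(faults = fault_model(clog_prob = 0.3), seed = 3)
ex
#> <rig_experiment: 28 feeds, 28 within tolerance, 0 alerts>
job_histogram(ex)
#>    kind
#> day aspirate cycle
#>   1        2     4
#>   2        2     4
#>   3        1     4
#>   ...
```

All 28 scheduled feed cycles (4 per day, 143 µL each, 4004 µL total) end
within tolerance; the clogs cost a handful of corrective feedback
aspirations and no alerts.

A command-line front end for the estimator lives at
`inst/cli/organoidrig.R` (`calibrate`, `estimate`, `validate-loo`).

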