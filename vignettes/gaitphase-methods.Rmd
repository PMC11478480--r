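---
title: "Continuous gait-phase estimation from insole force sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous gait-phase estimation from insole force sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gait phase locates a walker inside the gait cycle, here on a 0–100% scale
anchored at right heel strike. Estimating it continuously (every sample,
rather than detecting discrete events) underpins exoskeleton and prosthesis
control, gait-disturbance diagnosis and rehabilitation monitoring.
`gaitphase` implements a two-stage estimator driven purely by plantar load:
ten force-sensing-resistor (FSR) channels from a bilateral instrumented
insole (toe, first metatarsal, fifth metatarsal, cuboid, heel per foot),
sampled at 100 Hz. A first recurrent network classifies the walking
condition — level walk (LW), stair ascent (SA), stair descent (SD), ramp
ascent (RA), ramp descent (RD) — and its output is injected, together with
the FSR channels and regional force sums, into a second recurrent network
that regresses the phase.

## Model

Both stages share one architecture: two stacked bidirectional LSTM layers
with dropout 0.25 after each, a fully connected layer, and a task head. The
classifier (`wc_config()`) uses recurrent widths 128 and 64, a dense width
of 64 and a 5-class softmax over windows of 100 samples (1 s) of the 10
normalized channels, trained with categorical cross-entropy. The phase
estimator (`gpe_config()`) uses widths 128 and 32, a dense width of 2 and a
linear 2-unit output over windows of 25 samples, trained with mean squared
error. Both train with Adam (learning rate 0.001, batch 100) and early
stopping once validation loss fails to improve for 5 epochs; the classifier
additionally supports k-fold cross-validation over contiguous window blocks
(default 5), keeping the fold with the lowest validation loss.

Windows are causal: a window ends at the sample it predicts, so the
estimator never looks ahead. Windowed training pairs each window with the
label at its final sample, including windows that straddle a condition
change.

### Sine–cosine phase encoding

Regressing phase directly fails at the 0/100 wrap. The estimator therefore
predicts the continuous sinusoidal encoding
$(\cos\theta, \sin\theta)$ with $\theta = p\,2\pi/100$ (`encode_phase()`),
and predictions are decoded with the four-quadrant arctangent mapped to
$[0, 2\pi)$ (`decode_phase()`). A sign-based two-branch decode (using
$\tan^{-1}$ of the component ratio and reflecting when the sine component is
negative) is only well defined when the cosine component is positive; the
four-quadrant form agrees with it wherever it is defined and extends it
everywhere else, and is invariant to radial scaling, so raw network outputs
need not be unit norm. Encode/decode round-trip to below $10^{-9}$ phase
units; both properties are pinned by tests.

### Features

Channels are min–max normalized per channel with statistics fit on training
data only and frozen; held-out data is clipped to [0, 1]. No filtering or
smoothing is applied anywhere. From the normalized channels the per-foot
regional sums are formed — forefoot = toe + first + fifth metatarsal,
backfoot = cuboid + heel — each divided by its training-set maximum. Five
input variants are supported (`feature_width()`): #1 = 10 channels + 4 sums
+ 5-dim one-hot condition (19); #2 drops the condition (14); #3 drops the
sums (15); #4 keeps sums + condition only (9); #5 adds the two per-foot
centre-of-pressure coordinates to #1 (21). The centre of pressure is the
force-weighted mean of the anterior–posterior site coordinates (heel 0,
toe 1), holding its last value when total force drops below $10^{-6}$
(0 at series start).

Two width ambiguities were resolved in favour of the explicit feature
enumeration: the estimator input is the full 14 FSR-derived features plus
the 5-dim condition code (19), and its sequence length is 25 samples. Both
are configurable.

### Phase ground truth

Phase 0 is the right heel strike. `detect_heel_strikes()` finds upward
crossings of a threshold (default 0.05 normalized units) separated by a
refractory interval (default 300 ms), then walks each crossing back at most
10 samples to the last sample at or below a signal floor (default 0.02) so
the event lands at the onset of loading rather than at a threshold-dependent
instant partway up the rise; without the backtrack the label would carry a
systematic delay of about one sample (≈1 phase unit at comfortable
cadence). Between consecutive events the phase ramps linearly 0→100;
samples outside the first/last event are flagged invalid, never
extrapolated. On noise-free simulated data this labelling reproduces the
generator's phase to well below 1 phase unit (pinned by a test).

### Serial inference

`run_pipeline()` applies the classifier per sample (each window's label
assigned to its final sample and held until the next evaluated sample),
injects the hard one-hot of the argmax into the estimator features — class
probabilities behind `soft = TRUE` — and decodes the phase. During
*training* of the estimator the condition feature defaults to ground-truth
labels (teacher forcing), which decouples the stages and makes stage-2
quality measurable independent of stage-1 mistakes; training on stage-1
predictions is available by passing a fitted classifier. At inference,
stage-1 predictions are always used. Each stage normalizes raw input with
its own frozen statistics.

## The synthetic generator

No public recording set exists for this sensor layout, so the package ships
a simulator (`make_cohort()`, `simulate_trial()`, `simulate_protocol()`)
that stands in for a cohort study. Per channel and condition, one stride is
a smooth bump on the normalized phase axis: the heel an asymmetric bump with
a fast sin² rise pinned at phase 0 (a heel strike is an impact) and a
raised-cosine decay; the other sites raised-cosine bumps ordered
heel → cuboid → fifth/first metatarsal → toe through stance. Condition
templates differ the way stair and ramp loading differs from level walking:
SA is forefoot-dominant with a weak heel, SD has sharp heel/forefoot impacts
and little midfoot load, RA/RD are timing-shifted level-walk variants. The
left foot reuses the right-foot curves shifted by half a cycle.

Subjects differ by log-normal per-channel amplitude scales (SD 0.18),
cadence drawn uniformly from 48–60 strides/min (a comfortable self-selected
range), per-condition stance fractions around 0.60–0.64, and per-channel
timing shifts of the bump centres (SD 1.5 phase units) — except the right
heel, whose onset stays at phase 0 so the phase origin remains well defined.
Strides get Gaussian duration jitter (SD 15 ms) and the signal additive
Gaussian noise (SD 0.01 normalized units, about 1% of full scale, typical
of FSR front-ends; noise is truncated so forces stay non-negative — the
"no filters" rule means it is never smoothed away). Stride durations are
snapped to the 100 Hz grid so each heel strike falls exactly on a sample
and ground-truth phase is 0 there by construction; condition changes happen
at right-foot stride boundaries to keep the phase continuous across
segments.

The default protocol mirrors a multi-terrain course: three scenarios
(level-only; level/stair-up/level/stair-down/level; the same with ramps),
three trials each, with the third trial of every scenario held out for
testing and the remainder split 80/20 into contiguous training and
validation blocks — contiguous rather than shuffled so overlapping windows
cannot leak between training and validation.

What the generator does *not* emulate: calibrated force magnitudes in
newtons, double-support asymmetries, fatigue and speed drift within a trial,
paved/unpaved surface texture, sensor hysteresis and saturation. Passing
tests on this data therefore demonstrate that the pipeline, features and
training machinery are correct and that the architecture can learn
phase-locked plantar patterns — not that the printed accuracies of any
particular human cohort are reproduced.

## The bundled experiment

`run_synthetic_study()` is the package's reproducible end-to-end
experiment: 4 subjects × 3 scenarios × 3 trials, one shared condition
classifier, one phase estimator per subject, evaluation on the held-out
trials with stage-1 predictions feeding stage 2, and an own/cross-subject
grid aggregated per condition. Network sizes in this driver are reduced
(recurrent widths 24/12, classifier hop 12, estimator hop 4, ≤12 epochs):
the synthetic task is comfortably learnable at these sizes and the full
experiment then runs in minutes on a single CPU core, which makes it usable
as a routine regression check. The production-scale defaults remain those
of `wc_config()`/`gpe_config()`.

On this synthetic cohort the own-subject fit is high (phase R² well above
0.9) and cross-subject transfer is consistently worse — the same ordering
reported for human cohorts, driven here by the subject-specific amplitude
and timing parameters.

## Metrics

All phase errors are circular: $e = ((\hat p - p + 50) \bmod 100) - 50$, so
an estimate of 0.5 against a truth of 99.5 errs by 1, not 99. A non-circular
mode exists for comparison (`circular = FALSE`). `phase_error_metrics()`
reports, per condition and overall: RMSE in phase units; R² computed on the
sine–cosine pair (both components pooled, matching the regression loss; a
phase-domain R² would conflate wrap handling with fit quality); rRMSE =
RMSE / mean estimate × 100 (flagged undefined when the mean estimate is 0);
APEE = mean absolute circular error, which on the 0–100 scale is already a
percentage of the cycle (the metric is cited in the literature without a
formula; this is the natural reading, recorded here as this package's
definition); and NRMSE = RMSE / range × 100, which for a 0–100 phase equals
the RMSE numerically. Aggregates over conditions are unweighted means of the
five per-condition values (`overall_from_conditions()`), and own/cross
grids aggregate diagonal and off-diagonal cells per condition
(`aggregate_phase_grid()`). Every metric is pinned against brute-force
recomputation in the tests; a published ten-subject reference grid is
bundled (`reference_crosssubject_grid()`) as a worked aggregation example.

## Known limitations

* The simulator's stride templates are qualitative; absolute error numbers
  measured on synthetic data do not transfer to hardware.
* The left foot is features-only; a left-anchored phase would need its own
  labelling pass.
* Heel-strike detection assumes a clear heel rise; pathological gaits with
  forefoot-first contact would need a different anchor.
* Training is single-threaded and CPU-bound; the production-size stack on
  hours of data is a long run, which is why the bundled experiment uses the
  reduced sizes above.
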