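---
title: "Methods: forecasting and early warning of broiler-house thermal environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting and early warning of broiler-house thermal environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the two indicators

Environmental control in a cage-rearing broiler house aims at an
age-dependent target temperature; deviations in either direction stress the
birds, and heat combined with humidity stresses them further. `broodcast`
models two complementary indicators at the house level on a 5-minute grid:

* **TD**, the temperature deviation `Tin − Ttarget(age)`, which measures how
  far control has drifted from its set point (±2.5 °C is the accepted
  tolerance during transition/tunnel ventilation);
* **THI**, `(1.8·T + 32) − (0.55 − 0.0055·RH)(1.8·T − 26)`, a dimensionless
  thermal-load index; it increases strictly in temperature
  (∂THI/∂T = 1.8(0.45 + 0.0055·RH) > 0) and increases in humidity exactly
  when T > 26/1.8 ≈ 14.4 °C. Risk bands are Comfort (< 70), Warning
  (70–76), Danger (76–81), Emergency (≥ 81), lower edges inclusive.

Both are predicted 6 steps (30 minutes) ahead from the previous 36 steps —
enough lead time to act on ventilation, heating or spraying, short enough
for the non-stationary dynamics to remain predictable.

## From raw streams to a modelling series

Raw records from the robot, the fixed points and the outdoor station carry
their own timestamps. The pipeline (1) maps each source onto a common
3-second grid by nearest-neighbour matching, with deterministic tie-breaks
(an equidistant pair resolves to the earlier record; a record exactly
halfway between grid points goes to the earlier point) and a 1.5 s matching
radius; (2) collapses exact duplicates and resolves conflicting
same-timestamp records last-write-wins; (3) excludes values outside the
sensor measurement ranges (−20–50 °C, 0–100 %RH, 0.1–5 m/s, 300–5000 ppm);
(4) averages the remaining values per half-open 5-minute window
[t, t + 300 s), labelled by the window start; (5) fills interior gaps by
linear interpolation in time and edge gaps by the nearest valid value; and
(6) attaches the broiler age (days since flock start, floored) and the
target temperature.

The house-level indoor value averages the robot and all fixed points
(configurable to robot-only): the model predicts at the house level, and the
multi-source mean is the least committal estimator of the house state.
Aggregating an already-aggregated series is the identity, and the whole
chain is causal — editing records after time t never changes any value at
or before t.

Normalization is min–max to [0, 1] with statistics from the training span
only; test values outside the training range are deliberately *not* clipped,
because clipped extremes are exactly the events the warning engine must
see. A constant input channel (Age over a short span, Ttarget within one
age band) maps to 0 via a degenerate [x, x + 1] range rather than erroring;
a constant *target* is still an error, since its scaling is genuinely
undefined.

The chronological 80/20 split precedes all statistics. Supervised windows
slide with stride 1; a window belongs to the training set when its target
lies in the training span. Test-set windows may reach back into training
history for their inputs — that is exactly the deployment situation at the
split boundary — and a strict mode excludes them for leakage-audit
purposes.

## Causal wavelet features

At each step t the last W = 56 observations of the raw (physical-unit)
target series form a window; when fewer exist, the window is left-padded by
replicating the earliest observed value. A pyramidal DWT (db4 by default,
levels = 3, half-sample symmetric extension) decomposes the window, and the
final coefficient of the level-3 approximation band and of each detail band
becomes the 4-vector feature at t. Three choices deserve note:

* **Extension mode.** Causality is already guaranteed by the windowing; the
  extension only shapes boundary artifacts *inside* the window. Half-sample
  symmetric extension minimizes the discontinuity at the crucial right
  edge, and the filter-bank oracle in the test suite pins the convention
  (coefficient array lengths and phase) exactly.
* **W = 56 > L = 36 on purpose.** Each of the 36 input steps carries
  features computed from its own 56-step history, so the wavelet memory
  exceeds the model's direct window.
* **Features before normalization.** The decomposition runs on physical
  units and the resulting channels are min–max scaled with training-set
  statistics like any other channel. The transform is linear, so detail
  channels are unaffected by the shift and only rescaled.

The filters are the standard db2/db4/sym4 orthogonal pairs; analysis,
synthesis and the per-step feature track are all verified against an
independently written convolution/decimation oracle and against perfect
reconstruction to 1e-8.

## The forecaster

Input windows are L × C matrices. The **ECA** block summarizes each channel
by its temporal mean, runs a shared zero-padded 1-D convolution of odd
length k = |log2(C)/γ + b/γ|_odd (γ = 2, b = 1; floor, then bump even to
odd, minimum 1) across the channel axis, applies a sigmoid, and rescales
each channel by its weight — local cross-channel interaction without
dimensionality reduction. For the TD model C = 9 (5 screened + 4 wavelet
channels), giving k = 3.

The **GRU** iterates update/reset gates from h_0 = 0; the hidden state
after the last step is the sequence representation, mapped by a linear head
to the normalized prediction. Gate biases are included by default (the
bias-free textbook equations are available via `use_bias = FALSE`).
Training minimizes MSE on normalized targets with Adam (lr 0.001, batch 32,
up to 200 epochs), shuffling batches with the seeded generator, and stops
early when the chronological last 10 % of the training windows has not
improved for 20 epochs, restoring the best weights. Everything — parameter
initialization and shuffling — hangs off one `std::mt19937` seed, so a fit
is bit-reproducible on one machine.

The raw target series stays among the input channels alongside its wavelet
decomposition (the screened feature sets list it): the decomposition is
windowed and lossy at the boundary, so the raw channel is not redundant. A
switch drops it for ablation.

Baselines: **LSTM** (same hidden size and head), and a **TCN** of five
dilated causal convolution layers (kernel 3, dilations 1, 2, 4, 8, 16,
ReLU), receptive field 63 ≥ 36. Neither receives wavelet channels — they
are named without the Wavelet prefix — and only the `*eca*` variants carry
the attention block. All variants share the identical window/normalizer
path so comparisons isolate the architecture.

Metrics (MSE, MAE, RMSE, R²) are computed on de-normalized, physical-unit
predictions: a TD RMSE is a number of °C a manager can compare with the
±2.5 °C tolerance. Percentage reductions against the GRU baseline use
(base − variant)/base × 100 per metric.

## Warning engine

Real-time state identification labels each monitored value against the
age-dependent suitable band — Low / Normal / High with inclusive band
edges; CO2 has only an upper limit (Normal / OverLimit). Predictive
warnings label the *forecast*: TD strictly beyond ±2.5 °C raises a
heat/cold-deviation warning, and the THI level is read from its bands; both
are attached to every rolling prediction, one record per 5-minute step, and
can trigger simultaneously. These two outputs — per-location real-time
alarms and house-level predictive warnings — are kept separate.

Distribution statistics compare predicted and actual state streams over a
test period: per-state proportions (percent of n, two decimals), the
overheating frequency deviation |n̂_heat − n_heat| / n_heat × 100 (not
applicable when no actual heat state occurs), and the state-distribution
consistency (n − |Δheat| − |Δcold|)/n × 100. The consistency formula for
THI, which has four levels and no designated reference class, is the
distribution overlap (n − Σ|Δlevel|/2)/n × 100; the two coincide on the
two-sided TD case. These definitions reproduce the worked example bundled
in the tests (n = 596, proportions 6.38 %/6.71 % → deviation 5.26 %,
consistency 99.66 %) exactly, which is why they were adopted; they are an
interpretation, not the only possible one.

## The synthetic house

Real farm streams are rarely shareable, so the simulator generates the
conditions the pipeline was designed for, at the acquisition system's own
resolution: every terminal samples at 3-second intervals; the robot cycles
16 channels at 0.3 m/s (≈ 96 min per full cycle including turns), tagging
channel and cage; 12 fixed points carry persistent calibration-scale
biases; the outdoor station reports temperature, humidity and wind only.

The latent dynamics are deliberately simple and physical: indoor
temperature relaxes first-order (time constant 30 min) toward the age
target plus a fraction (0.15) of the diurnal outdoor anomaly (amplitude
6 °C around 24 °C — early-summer conditions in a temperate broiler region)
plus square pulses for equipment start-stop events (8/day, 0.5–1.5 °C,
10–30 min); humidity is anti-coupled to temperature around the age band
midpoint; CO2 rises with bird age and at night when ventilation drops.
Observation noise is Gaussian (0.3 °C, 2 %RH); latent process noise and
spatial biases scale with the observation noise so that zero noise yields a
fully deterministic path. Missing CO2 cells are injected at rate 0.0226 and
out-of-range invalid values at rate 0.002, flagged in a hidden truth column
so filter tests have labels. All values were chosen once from the stated
acquisition conditions and generic poultry-house physics.

What the simulator does **not** emulate: spatial gradients along the house
beyond per-source biases, bird-behavior feedback on heat production,
ventilation-controller dynamics, sensor drift, or regime changes between
seasons. Passing tests on synthetic data therefore demonstrates that the
pipeline and models are implemented correctly and can learn these dynamics
— not that the error magnitudes transfer to any particular real house.

## Benchmark scale and reproducibility

The bundled benchmark simulates 14 days, runs the full raw-records path
(about 5.6 million records), and trains the flagship and GRU baselines with
hidden width 32 over five model seeds on one fixed scenario at a reduced
50-epoch cap, reporting median test RMSE (~800 test windows per run). These
sizes keep a desk run in the minutes range while leaving enough data and
training budget for every variant to converge to its typical error.
The 30-minute-ahead median RMSE is compared against 1.5× the
injected observation noise sd — beating that bound requires the model to
have learned the deterministic part (relaxation, diurnal forcing) well, as
the residual unpredictability (pulse onsets within the horizon, accumulated
process noise, aggregated observation noise) is engineered below it.

Known limitations: single-layer recurrent stacks only; single-step (t+H)
prediction rather than multi-horizon sequences; no hyperparameter search;
the TCN baseline's width/dilation schedule is fixed by convention rather
than tuned; and error magnitudes reported for real farm deployments cannot
be reproduced here because such datasets are not public — the package's
claims about real data are therefore structural (implementation
correctness, causality, leak-freedom), not numerical.
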