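---
title: "Classifying instrumented-mouthguard captures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying instrumented-mouthguard captures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(impactkit)
```

## The problem

Instrumented mouthguards record short, threshold-triggered windows
("captures") of head kinematics during contact sport. Only a fraction of
captures are genuine head or body impacts; the rest are artifacts of
wearing the device — biting and chewing, yelling, handling the mouthguard.
Telemetry systems that count every capture as an impact overstate exposure
badly, so a classifier that separates *hits* from *non-hits* is the core of
any usable exposure-monitoring pipeline.

`impactkit` implements such a pipeline end to end: a capture data model and
file dialect, an onboard-trigger emulator, a triage filter, two
feature families (random convolutional kernels and binned Welch power
spectral densities), class balancing and stratified splitting, an untuned
baseline sweep, MCC-optimized randomized tuning of a gradient-boosted tree
ensemble, bootstrap confidence intervals for the reported metrics, and
TreeSHAP-based attribution summaries. Because the match data this design
derives from are proprietary, the package ships a synthetic capture
simulator so that every stage is testable, and the whole pipeline can be
exercised and audited on corpora with known ground truth.

## Sensor and capture model

The device model carries three triaxial accelerometers (left, centre,
right; ±200 g, 12-bit, nominally 3,200 Hz) and one triaxial gyroscope
(±2,000 dps, 16-bit, nominally 800 Hz). A capture begins 20 ms before the
first sample whose *raw* left-accelerometer norm reaches 10 g and ends
80 ms after the last such sample; triggers closer together than the tail
merge into a single capture, so one capture can hold several impacts.
Samples are stored in physical units (g, dps); quantization to the sensor
bit depth is applied only in the simulator. `trigger_index` is 0-based on
the stored left-accelerometer stream at its actual rate.

Captures live in a self-describing `.captures.json` file (one session per
file, JSON header plus per-capture columnar sample blocks, full-precision
doubles). The dialect is diffable and dependency-free; a columnar binary
backend could mirror it without changing the contract.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the corpus conditions: ~10:1 non-hit:hit
imbalance (`hit_fraction = 0.115`), impact amplitudes 10–150 g with
dominant frequency 20–150 Hz, ±1% sampling-rate jitter, 0.3 g sensor
noise, and an artifact mix of chewing (0.5), yelling (0.3) and handling
(0.2). The waveform families are deliberately minimal models of the
frequency structure each class needs:

* **impact** — an exponentially damped sinusoid (decay 15 ms), normalized
  so its peak equals the drawn amplitude, projected on a random unit axis
  shared by the accelerometers, with a rotational pulse on the gyroscope
  whose amplitude is proportional (6 dps per g) on a random axis. No
  rigid-body lever-arm model is attempted.
* **chewing** — a 1.5 Hz burst train carrying a 10–30 Hz component (4–14 g)
  plus a 400–800 Hz "deformation ripple" (6–18 g). Some chewing events
  exceed 10 g after filtering and therefore survive triage, as they must:
  real post-triage corpora still contain chewing captures.
* **yelling** — a narrowband 480–700 Hz carrier with a Hann envelope. The
  norm of a fixed-axis carrier rectifies to a DC component of about
  0.64 × amplitude, so amplitudes are drawn in 10.5–13 g: above the 10 g
  raw trigger, below the 10 g triage threshold after the 300 Hz filter.
* **handling** — 2–5 irregular broadband spikes (Gaussian envelopes of
  1–3 ms) of 8–30 g.

Artifact amplitude and frequency ranges are stated defaults, not claims
about any particular sport: the source data never published them. The
simulator reproduces the *spectral separation* the pipeline exploits; it
does not attempt biofidelic skull/neck dynamics, helmet attenuation, or
athlete-specific variation. A pipeline that is perfect here can still be
much weaker on real captures, where classes overlap spectrally; passing
tests demonstrate that the machinery is correct, not that the problem is
easy.

Each capture derives its own RNG seed from the corpus seed and the capture
counter, so corpora are reproducible regardless of generation order, and
events that never reach the trigger are redrawn within their class.

## Preprocessing choices

* **"Non-phase corrected"** is read as a causal single-pass filter (the
  contrast is with zero-phase forward–backward filtering). The triage
  filter is a second-order Butterworth low-pass at 300 Hz applied to the
  left-accelerometer norm, then re-thresholded at 10 g.
* The **onboard trigger operates on the raw norm**; filtering belongs to
  the later offline triage stage.
* **Resampling** to the common 3,200 Hz rate uses polyphase filtering; a
  jittered rate is first approximated by a rational ratio with denominator
  ≤ 1,000. All 12 aligned channels are trimmed to a common length after
  resampling. Windows clipped at stream edges are kept, not discarded.
* Axis alignment applies per-sensor rotation matrices supplied as inputs
  (orthonormal, determinant +1); their derivation is out of scope.

One numeric caveat worth knowing: the discrete (bilinear-transform)
Butterworth matches the analog magnitude response closely through the
passband and lower stopband, but near Nyquist it rolls off much faster
(gain ≈ 9×10⁻⁴ at 1,500 Hz versus 0.04 for the analog formula). Tests
check the exact prewarped closed form
$1/\sqrt{1+(\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^4}$.

## Feature generation

Two families, computed on all 12 aligned signals of each triage-passed
capture:

* **Random convolutional kernels.** Lengths drawn from {7, 9, 11},
  standard-normal mean-centred weights, bias uniform on [−1, 1], dilation a
  power of two capped so the receptive field fits a 320-sample capture,
  zero padding with probability ½. Each signal is z-scored to its own mean
  and SD before convolution; per kernel the maximum output and the
  proportion of positive outputs are kept. The reference configuration
  draws **one shared set of 300 kernels** applied to every signal — 600
  features per signal. (The printed totals in the source material are
  internally inconsistent — 300 kernels × 2 statistics × 12 signals is
  7,200, not 720 — so the per-signal count is configurable and the
  reference follows the operational statements.)
* **Binned log Welch PSD.** Welch's method with 256-sample segments, 50%
  overlap, periodic Hann window, per-segment constant detrend, one-sided
  density scaling — and a 640-point zero-padded FFT. The zero padding puts
  the frequency grid at 5 Hz so that every 10 Hz bin in (10, 1600] Hz
  contains frequencies; at the natural 12.5 Hz resolution a fifth of the
  bins would be empty. The characteristic value of a bin is the **mean**
  PSD inside it (scale-stable under bin occupancy), floored at 10⁻³⁰
  before the natural log. This yields 159 features per signal, 1,908
  across the 12 signals.

Features are standardized to the mean and population SD of the training
subset only; zero-SD columns map to zero under an ε-guard.

## Dataset construction

Balancing keeps every minority-class capture and downsamples the majority
uniformly without replacement. The balanced set splits per class:
⌊0.70 · n⌋ training captures, the remainder split evenly between
validation and test with an odd remainder going to validation. (The
reference cohort's published validation/test counts are not consistent
with any exact stratified 15%; the clean rule above is used and observed
counts are logged.) The *rest* set holds the majority-class captures
excluded by balancing — the real-world ~10:1 specificity probe — and the
*holdout* set is always a designated held-out session, never a random
draw.

## Modeling

The untuned baseline sweep fits every roster entry with library defaults
on the training subset and scores TP%/TN% on the validation subset;
failures are recorded and skipped. The selection rule maximizes
mean(TP%, TN%) with ties broken by the smallest |TP% − TN%| (the published
criterion states the intent, not the formula; this is the obvious
formalization), then by roster order.

Randomized tuning scores candidates by mean Matthews correlation
coefficient over stratified k-fold cross-validation (reference: 50
candidates, 5 folds — 250 fits plus one refit; the "500 fits" sometimes
quoted for this recipe double-counts). The first candidate is always the
library-default configuration, so tuning can never select a model that
cross-validates worse than the untuned baseline. The declared space is:

| parameter | range |
|---|---|
| boosting rounds | 50–200 |
| max depth | 2–8 |
| learning rate | log-uniform 0.03–0.3 |
| row subsample | 0.5–1 |
| column subsample | 0.2–0.8 |
| min child weight | 1–10 |

with `tree_method = "hist"`, `max_bin = 63`. The column-subsample range
sits below the classical 0.5–1 band, and rounds are capped at 200, because
the reference feature matrix is very wide (up to 9,108 columns) relative
to training sets of a few hundred captures: stronger column subsampling
regularizes, and on a single CPU it bounds the cost of the
250-fit search. Both choices were made once, as the package's declared
space.

## Evaluation

TP% = 100·tp/(tp+fn), TN% = 100·tn/(tn+fp), sensitivity, precision, F1 and
MCC are computed per subset, each with a percentile bootstrap 95% CI over
10,000 resamples. Resampling (truth, prediction) pairs uniformly with
replacement induces a multinomial distribution over the four confusion
cells, so for confusion-based metrics the resampled counts are drawn
directly from that multinomial — distributionally identical to pair
resampling and orders of magnitude faster; arbitrary metric functions fall
back to explicit index resampling. Degenerate denominators follow a
0-with-flag convention (the rest set has no positives by construction, so
its TP% and F1 print as 0.00 and are flagged). Report tables print rates
truncated — not rounded — to two decimals, matching the convention of the
reference tables; serialized reports keep full precision.

## Attribution

Per-observation additive attributions come from the tree library's exact
TreeSHAP (`predict(..., predcontrib = TRUE)`); this module owns only the
ranking (mean |attribution|, top-k), the signed per-observation values,
and grouping by feature family, sensor, or PSD frequency band (split at
150 Hz). Contributions are computed in float32, so the additivity
reconstruction |Σ attributions + base − margin| carries an error of order
|margin| × 2⁻²³; for confident ensembles this can reach ~10⁻⁶ in absolute
terms. Hit-direction mass (the mean positive part of each feature's
attribution) is the statistic used to ask which frequency band pushes the
model toward the hit label.

## Problem sizes used by the test suite and acceptance script

The shipped end-to-end run uses a 2,000-capture corpus at the default
simulator settings, the full 1,908 PSD bins with 100 kernels per signal,
and a 15-candidate × 3-fold search. These sizes were chosen once as a
desk-scale configuration that exercises every stage; the 300-kernel
reference feature layout is verified separately on a small corpus, and the
bootstrap-coverage check uses 600 outer replications so the Monte-Carlo
error of the coverage estimate is below half a point.

## Known limitations

* The simulator's classes are spectrally well-separated by construction;
  real captures are harder, and reported synthetic performance should not
  be read as a claim about field performance.
* The rotational channel is a proportional coupling, not a rigid-body
  model; angular-acceleration crosschecks between the three accelerometers
  are not implemented.
* The attribution frequency-band summary is seed-sensitive on synthetic
  corpora: both bands carry discriminative information, and which
  dominates can vary with the simulated draw.
* Stored captures are assumed to be in physical units; raw-count ingestion
  would need a conversion layer in front of `read_capture_file()`.
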