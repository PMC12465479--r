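---
title: "Localizing the motor hotspot from movement-related EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the motor hotspot from movement-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcranial electrical stimulation of the hand motor area is usually
targeted either at the 10-20 electrode positions C3/C4 or at the *motor
hotspot* — the scalp site where transcranial magnetic stimulation (TMS)
elicits the largest motor evoked potential in the first dorsal
interosseous muscle. Individual hotspots sit a couple of centimetres away
from C3/C4 on average, so electrode-based targeting is systematically off,
while TMS-based hotspot hunting needs hardware and expertise that
rehabilitation settings often lack.

`hotspotEEG` implements an EEG-only alternative: a deep two-dimensional
convolutional network regresses the hotspot's 3D coordinates (mm, in a
head frame with its origin at the vertex electrode Cz, +x toward the right
preauricular point, +y toward the nasion, +z up) from single trials of
movement-related EEG. The package covers the complete workflow — montage
geometry, EDF input/output, a five-level preprocessing ladder, per-subject
model training inside a nested cross-validation, Euclidean error-distance
scoring, channel/trial ablations, and nonparametric statistics — together
with a seeded simulator that generates movement-EEG cohorts with *known*
hotspot locations, so that the whole pipeline can be validated by
parameter recovery.

## Head model and montages

Electrodes live on a sphere of radius 90 mm whose top is Cz; the 10-20/
10-10 positions are built from the classical arc construction (midline
electrodes every 18 degrees along the nasion-inion arc, an outer ring at
72 degrees inclination, intermediate electrodes by quarter-subdivision of
the great-circle arc from the midline electrode of a row to its ring
electrode). Two montages are shipped: `healthy63` (63 data channels at
1000 Hz; Fpz and FCz serve as ground and reference and are not data
channels) and `stroke29` (29 channels at 500 Hz). Because the frame's
origin is on the scalp, ear-level electrodes are `sqrt(2) * 90` mm from
the origin; position validation uses that bound, not the head radius.

Channel sets nest from the full montage down to a compact motor-area set:
healthy `Set5` is the 9-channel block `FC5/FC3/FC1/C5/C3/C1/CP5/CP3/CP1`
(mirrored for the left hand), stroke `Set3` the 5-channel block
`FC5/FC1/C3/CP5/CP1`. The intermediate sets are reasonable nested
reconstructions (full montage -> fronto-centro-parietal rows -> FC/C/CP
rows -> contralateral half) and can be overridden per experiment, since
only the largest and smallest sets are pinned down precisely by the
protocol.

## The synthetic cohorts

No public clinical dataset accompanies this method, so validation uses a
simulator whose defaults encode the study conditions:

| parameter | healthy | stroke | meaning |
|---|---|---|---|
| `fs` | 1000 Hz | 500 Hz | acquisition rate |
| `n_trials` | 30 | 30 | movement trials per hand |
| inter-trial interval | 3-7 s | 3-7 s | uniform relaxation period |
| event type | key press | visual cue | epoch anchor |
| `snr` | 5 | 3.5 | burst/background RMS at the best channel |
| `spatial_sigma` | 20 mm | 20 mm | Gaussian footprint width |
| `hotspot_offset_mean` | 24.36 mm | 35.56 mm | tangential displacement from C3/C4 |
| `hotspot_jitter_sd` | 6 mm | 12 mm | tangential jitter SD |
| `artifact_rate` | 6/min | 6/min | blink rate |

Each subject's hotspot is drawn by displacing the contralateral C3/C4
position along the anterior-lateral scalp tangent and jittering it
isotropically in the tangent plane before reprojecting to the sphere. The
offset defaults were calibrated by Monte Carlo so that the mean 3D
hotspot-to-C3/C4 distance reproduces the cohort means reported for
TMS-defined hotspots — 24.31 mm in healthy adults and 34.96 mm in stroke
patients (the stroke preset also halves nothing else: it lowers SNR by
30% and doubles the jitter to echo the wider hotspot scatter). Each trial
adds a 0.4 s Hann-windowed 30-50 Hz band-limited noise burst — centred at
the key press (healthy) or 0.3 s after the cue (stroke, movement
latency) — whose per-channel amplitude follows a Gaussian function of the
3D distance between electrode and hotspot
(`gain = exp(-d^2 / (2 * 20^2))`, max-normalized). The background is
per-channel 1/f noise band-limited to 1-55 Hz at 10 uV RMS plus a rank-3
shared component at 20% RMS (a stand-in for volume conduction), and
blinks are 300 ms biphasic transients weighted by each electrode's
anterior position.

The kernel footprint is a *surrogate* forward model: it makes the hotspot
location identifiable from channel-space gamma topography, which is the
property the network exploits. It does not model realistic leadfields,
alpha/beta event-related desynchronization, EMG, or patient-specific
lesions. Passing recovery tests on these cohorts therefore demonstrates
that the pipeline is correct and information-efficient — not that the
method achieves any particular accuracy on clinical EEG.

## The preprocessing ladder

Five model inputs of increasing refinement are defined, each produced by a
cumulative stage chain:

1. `Input_1` — downsampled raw data, epoched (channel x time),
2. `Input_2` — + common average reference (CAR),
3. `Input_3` — + zero-phase 3rd-order Butterworth band-pass, 1-55 Hz,
4. `Input_4` — + ICA artifact removal,
5. `Input_5` — + gamma-band (30-50 Hz) power spectral densities
   (channel x 21 bins).

Numerical choices worth knowing:

* All levels are first downsampled to 200 Hz so tensor widths are
  comparable across cohorts; integer ratios use an 8th-order Butterworth
  anti-alias low-pass (forward-backward) plus decimation, the non-integer
  500 -> 200 ratio uses exact Fourier resampling after r-signal's
  polyphase `resample()` failed a 1% amplitude oracle on a 10 Hz tone.
* CAR and ICA act on the full montage; channel-set restriction happens
  after epoching.
* Zero-phase filtering composes a forward and a backward pass, so the
  effective magnitude response is the squared one-pass Butterworth
  response. The reversal identity `filter(rev(x)) == rev(filter(x))`
  holds up to edge transients; the 1 Hz corner has a long impulse
  response, so tests compare the central section of long signals.
* The ICA stage is extended Infomax (natural-gradient block updates with
  a per-component super/sub-Gaussian sign, learning-rate annealing on
  update-direction reversals plus a small unconditional anneal per pass so
  that the iteration terminates). Components are rejected automatically
  when their time course correlates above 0.7 in absolute value with the
  frontal blink proxy (mean of Fp1/Fp2) or their kurtosis exceeds 8; the
  manual visual inspection used in clinical practice is not testable, and
  both thresholds are exposed as arguments.
* Epochs are (-0.5, 0.5) s around key presses (healthy) or (-0.5, 1.0) s
  around cues (stroke); trials whose window leaves the recording are
  dropped with a warning, not padded.
* PSDs are magnitude-squared FFTs with a rectangular window, zero-padded
  to the next multiple of `fs / resolution` samples so 1 Hz bins fall on
  exact integer frequencies; band endpoints 30 and 50 Hz are inclusive
  (21 bins). The stroke epoch (1.5 s at 200 Hz) is padded to 2 s.

## The network and its training

The regressor is a 17-layer 2D CNN: four blocks of (2, 2, 3, 3) stride-1
7x7 convolutions with (16, 16, 32, 32, 64, 64, 64, 128, 128, 128)
filters, each block closed by a 2x2/stride-2 max-pool (ceiling semantics
with zero padding), then dense layers of 256, 64 and 3 units. All hidden
activations are ReLU; the output layer is linear. Convolutions use
shape-preserving padding — with ten stacked 7x7 kernels, valid-mode
convolution would annihilate the 9-channel axis of the compact channel
sets. The two intermediate dense widths are not pinned by the protocol
and are configuration-exposed, as is the whole block structure (reduced
profiles are used for cheap experiments).

Training minimizes MSE with ADAM (learning rate 0.001, batch size 10, up
to 1000 epochs) and early stopping after 20 epochs without validation
improvement, restoring the best-epoch weights. Two numerical choices
matter:

* Inputs are standardized per channel with statistics computed on the
  training trials only and reused for validation/test trials, so no
  leakage enters through the scaler; a zero-variance channel falls back to
  unit scale with a warning.
* Targets are expressed in head-radius units (coordinates / 90 mm) inside
  the fitter, and predictions and losses are mapped back to mm. ADAM's
  per-parameter step size is invariant to loss scale, so reaching a
  ~50 mm coordinate from zero-centred initial weights takes thousands of
  updates when targets are left in mm; in head-radius units the same
  optimizer converges within the epoch budgets used here. Reported
  history is in mm^2 either way.

The engine is written in Rcpp/RcppArmadillo (single-precision, one
im2col GEMM per convolution per batch) because no deep-learning framework
is available in this R stack — and because the regressor is the core of
the method, it is implemented and audited explicitly, layer by layer
(`build_model()` emits a layer report with kernel, filters, stride, and
output shape per layer). All randomness (weight initialization, batch
shuffling, fold assignment) flows through R's RNG, so fits are exactly
reproducible from a seed.

## Evaluation protocol

Each subject-and-hand dataset (30 trials) is evaluated by trial-wise
nested cross-validation: 5 repetitions of 5 outer folds (25 evaluations);
each outer fold holds out 20% of trials, the remaining 80% are split 4:1
into training and validation (24 -> 19 + 5; in general the validation
share is `max(1, round(n/5))`), a model is trained from scratch per fold,
the subject-level prediction is the mean over the outer-test-trial
predictions, and the fold error is the Euclidean distance to the ground
truth in mm. Fold assignment is seeded per repetition and stored with the
result for exact replay; the accounting (disjoint, exhaustive outer test
sets; no train/validation/test overlap) is asserted at run time and in
the tests. Datasets pool hands — a subject's left-hand and right-hand
recordings count as independent datasets, matching how cohort means are
usually reported for this task.

Ablations subsample trials without replacement using one seeded
permutation per dataset, taking the first *k* entries, so smaller trial
sets are nested within larger ones; channel ablations restrict the epoch
tensor to a channel set; input-level ablations switch the preprocessing
ladder. Condition summaries report mean ± SE over datasets. Stroke-cohort
experiments use raw input (`Input_1`) only, mirroring the clinical
protocol choice.

Paired condition comparisons use a Friedman omnibus across three or more
conditions and pairwise Wilcoxon signed-rank post-hocs (exact
distribution for n <= 25 pairs, normal approximation above), unpaired
comparisons use rank-sum tests, and pairwise p-values are
Bonferroni-multiplied and capped at 1. Fully tied inputs (identical
condition vectors) are reported as statistic 0, p = 1.

## Benchmark profiles and problem sizes

Two stock experiments summarize the package's validation; both are
exported functions used by `scripts/acceptance.R` and the test suite:

* `recovery_benchmark()` — 10 healthy synthetic subjects (right hand,
  SNR 5), `Set5`/`Input_1`, the full 17-layer network with the epoch cap
  at 100, one outer fold per subject. The reference is the leave-one-out
  mean-coordinate predictor over the cohort's true hotspots — the best
  EEG-blind guess, which lands around the hotspot prior's spread
  (~8-10 mm). The network's recovery error is typically a fraction of a
  millimetre, far below half the baseline.
* `trial_trend_benchmark()` — 10 seeds x 3 subjects x {30, 10, 5}
  trials with a reduced profile (two conv blocks of 8/16 filters, dense
  32-16-3, a fixed 40 epochs), two outer folds per dataset. Mean error
  increases monotonically as trials are removed, echoing the trial
  ablation findings on clinical data.

These sizes are the package's chosen desk-scale defaults: one outer fold
per subject in the recovery benchmark (the constant-target fold structure
makes the remaining 24 folds near-redundant for a cohort-level summary)
and a reduced network for the trend (the full architecture's per-fold
cost adds nothing to a monotonicity comparison). Both functions accept
larger sizes.

## Why per-subject training recovers hotspots so precisely

One property of the protocol deserves emphasis: within one subject all 30
trials share a single target coordinate, so the per-subject network
effectively has to memorize a constant — the EEG input determines how
quickly and how stably it can do so under trial-wise cross-validation,
and trial-averaged predictions are extremely precise once training
converges. Sub-millimetre mean errors on the synthetic preset (and in
clinical reports of this protocol) should be read in that light: the
meaningful comparison is against the EEG-blind baseline and across
ablation conditions, not against the physical size of cortical targets.

## Known limitations

* The spherical head model and Gaussian footprint are deliberate
  simplifications; no individual anatomy, leadfield, or MRI coregistration
  is modelled.
* ICA rejection is automated with fixed default thresholds; clinical
  pipelines typically add visual review.
* The EDF writer targets this package's needs (16-bit, 1 s records, an
  integer-coded `Events` signal, exact sample count in the reserved header
  field); it does not implement EDF+ annotations.
* Training is CPU-only by design; the full 17-layer network trains one
  fold of one subject in tens of seconds on one core, which is adequate
  for the benchmark sizes above but not for large grids at full CV depth.
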