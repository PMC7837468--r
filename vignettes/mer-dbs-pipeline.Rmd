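---
title: "Predicting DBS motor outcome from microelectrode recordings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DBS motor outcome from microelectrode recordings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bilateral subthalamic deep brain stimulation (STN DBS) improves motor
symptoms in advanced Parkinson's disease, and the benefit depends on where
the stimulating contact ends up. During implantation, microelectrode
recordings (MER) — single-channel extracellular voltage traces sampled at
48 kHz — are taken at sub-millimetre depth steps along the trajectory.
`merdbs` implements a pipeline that asks whether the MER trace recorded at
the eventually active contact already predicts the patient's *motor response
class* six months later.

The clinical endpoint is the lateralized UPDRS part III subtotal measured
off-medication with stimulation on versus off:

> ratio = UPDRS III (DBS on) / UPDRS III (DBS off), at 6 months

Lower is better. The ratio is dichotomized with side-specific thresholds:
*good* response below 0.70 on the left body side and below 0.60 on the
right; the intervals are half-open, so 0.69 (left) and 0.59 (right) are
good. Ratios above 1 — worsening under stimulation — are classed moderate;
this extends the printed 0–1 ranges, and the generator clips ratios to
[0, 1.2] so such cases survive labeling. Because only left-hemisphere MER is
analyzed, the right body side is *contralateral* (the side the recorded
hemisphere mostly controls) and the left *ipsilateral*.

Each lead contact spans 1.5 mm while MER is stepped at 0.5 mm, so three
consecutive recordings map to one contact and hence to one clinical outcome:
segments come in depth triplets sharing a label.

## Pipeline

1. **simulate** — a synthetic MER cohort (real patient recordings are not
   publicly available) with controllable band-specific content causally
   coupled to bilateral outcomes;
2. **preprocess** — Morlet continuous-wavelet-transform scalograms in three
   bands (1–50, 50–500, 500–5000 Hz), resized to the classifier input;
3. **label** — on/off ratios, per-side dichotomization, patient-level
   train/test splits;
4. **train** — a VGG-style shared-trunk CNN with two task heads
   (contralateral, ipsilateral) and a weighted joint cross-entropy;
5. **evaluate** — max-accuracy epoch selection, band comparison, loss-ratio
   sweep, ROC/AUC, late-training stability, bilateral correlations.

`run_experiment()` chains the stages under one global seed;
`inst/cli/mer-dbs.R` is a thin shell wrapper.

## Wavelet preprocessing

The CWT of a signal $s(t)$ is

$$W(a, b) = \frac{1}{\sqrt{a}} \int s(t)\, \Psi^*\!\Big(\frac{t-b}{a}\Big)\,dt,
\qquad \Psi(t) = \pi^{-1/4} e^{i\omega_0 t} e^{-t^2/2},$$

with scale $a$ inversely proportional to frequency. Choices, since several
were unstated in the source analysis:

* **ω₀ = 6**, the standard Morlet center frequency at which admissibility
  holds to good approximation; scale↔frequency via the center-frequency
  rule $f = \omega_0 / (2\pi a)$.
* **"resolution of 8"** is read as 8 voices per octave on a dyadic grid
  (the most common meaning); it is a `morlet_params()` knob if that reading
  is wrong. At 8 voices the grid step is $2^{1/8}$, so a pure tone's peak
  row is within ~4.4% of its true frequency — the basis of the 5%
  peak-recovery tolerance.
* **Band selection by scale**: the three bands are produced by restricting
  the scale grid, not by pre-filtering; a zero-phase 4th-order Butterworth
  `bandpass()` (hand-implemented as cascaded biquads — no DSP filter-design
  package is available) can be applied first via `prefilter = TRUE`, since
  the source describes both at different points.
* **Normalization order**: the raw signal is min-max normalized to [0, 1]
  first, then transformed, then the magnitude image is min-max normalized —
  "normalized to 0–1" is ambiguous between the two, so both are applied and
  each is toggleable. Note the signal normalization adds a DC offset whose
  windowed spectrum lands in the lowest band; tests of band confinement use
  `signal_norm = FALSE`.
* **Edges**: the signal is treated as zero outside its support and edge
  effects are retained (no cone-of-influence masking). The Morlet kernel is
  truncated where its envelope falls below $e^{-32}$, so the FFT-based
  transform matches a direct evaluation of the discretized integral to
  better than $10^{-6}$ relative error (asserted in the tests).
* 60-Hz line noise is deliberately **not** notch-filtered.
* Images are resized bilinearly; 224×224 suits the full VGG16 configuration
  and 64×64 the desk-scale one.

Two physical caveats the tests revealed, worth knowing when interpreting
band experiments: Morlet filters have relative bandwidth ≈ 1/ω₀, so signal
content flush against a band edge bleeds into the neighbouring band's
scalogram; and for short segments the abrupt ends scatter broadband energy
into the lowest-frequency rows ("edge splatter"), which lets a loud
band-limited component leave a faint signature outside its band. Band
separation is therefore good but not absolute, and the band-comparison
acceptance test asserts an ordering, not perfect exclusion.

## The synthetic cohort

The generator emulates the cohort structure the analysis assumes: ~34
patients averaging ~20 segments each (a cohort configured to 696 segments
over 34 patients reproduces the 20.47 segments/patient mean exactly),
bilateral outcome ratios on the clinical scale, and a band-specific signal
feature that drives the contralateral outcome more strongly than the
ipsilateral one.

Per patient: a binary latent class (good/moderate-leaning, p = 0.5) and a
continuous feature $x = 1 + 0.3\,(\text{effect\_size}\cdot c + z)$,
$z \sim N(0,1)$. Both on/off ratios are affine in $x$:

$$r_{\text{side}} = \alpha_{\text{side}} + 0.5\,\kappa_{\text{side}}
  (x - \bar{x}) + u + \varepsilon_{\text{side}},$$

with intercepts at the side's own threshold (0.60 contralateral, 0.70
ipsilateral), couplings $\kappa$ defaulting to 1.0 (contra) and 0.5 (ipsi),
independent noise $\varepsilon \sim N(0, 0.12^2)$ and a shared patient-level
noise $u$ whose variance is solved in closed form (monotone root-finding on
the exact pre-clipping correlation) so the left/right ratio correlation hits
`bilateral_corr_target` (default 0.67, the clinically reported value). The
default `ratio_noise_sd = 0.12` was chosen once so that the
feature-induced correlation alone stays below that target, leaving the
calibration a positive root. Ratios are clipped to [0, 1.2].

Waveforms are a sum of: 1/f-shaped broadband background; a beta-band
(13–30 Hz) oscillation (the low-band carrier — beta power in the dorsal STN
is a known response predictor); band-limited Gaussian "multi-unit" noise at
80–350 Hz (inset from the 50/500 Hz edges for the bandwidth reason above);
a Poisson-bursting spike train convolved with a 1.2-ms biphasic template
(spike energy ≈ 0.8–2 kHz); and a small optional 60-Hz mains sinusoid. The
component in `effect_band` has amplitude proportional to the patient's
feature level; the others stay at base amplitude.

Pre-operative and 6-month off-stimulation UPDRS III scores are drawn on the
clinical scale (means ≈ 12.4/12.8 and 11.2/11.5, SD ≈ 5 and 4.4, truncated
at 0) with left/right correlations ≈ 0.77 and 0.74 respectively, and are
statistically independent of the ratios — reproducing the reported null
relationship between baseline severity and stimulation benefit. On-state
scores are `ratio × off`, and scores are kept continuous (not rounded to
integer UPDRS points) so the stored ratio is exactly on/off.

What the generator does *not* emulate: biophysical STN neuron dynamics,
anesthesia effects, multi-electrode geometry, non-stationarity within a
trajectory, or integer-valued ratings. A green test therefore establishes
that the pipeline recovers structure *of the kind assumed*, not that it
would perform equally on real recordings.

## Classifier

The trunk is a VGG-style stack of 3×3 stride-1 convolutions with ReLU and
max-pooling between blocks, shared by two task-specific fully connected
heads of widths 120, 120, 16, 2 with dropout 0.2 after each hidden head
layer (the source states the rate but not its placement; per-hidden-layer is
the default reading). The joint loss is

$$L = w_c\,\mathrm{CE}(\text{contra}) + w_i\,\mathrm{CE}(\text{ipsi}),$$

softmax cross-entropies averaged over the batch, with **no weight
normalization** — only the ratio $w_c\!:\!w_i$ is semantically meaningful,
and scaling both weights scales every gradient, which is part of what a
loss-ratio sweep with plain SGD measures. "Gradient descent optimizer" is
implemented as plain mini-batch SGD without momentum; batch size (unstated)
defaults to 32. No pretrained weights are used (none are mentioned);
initialization is fan-in-scaled Gaussian.

Seeds: one model seed derives independent streams for trunk initialization,
each head's initialization and dropout, and epoch shuffling, so a
single-task model coincides bit-for-bit with the first head of a multitask
model, and a `w_ipsi = 0` multitask run reproduces single-task training
step for step (asserted in the tests). Patient-leakage between train and
test is asserted inside `fit_classifier()` itself, independently of the
labeling module.

The full-size `model_config_vgg16()` (224×224, 13 conv layers, lr 0.001)
is the published architecture and is far too large for CI; the desk-scale
configuration (64×64, one 4-channel block, pool 4) uses lr 0.005,
calibrated once on the generator's stated world: 0.05 collapses to dead
ReLUs under the 5:1-weighted loss, while 0.005 trains stably. With plain
SGD at this rate the training loss typically does not reach the 0.05
"nearly zero" gate within 60 epochs, so max-accuracy selection takes its
documented relaxed path (all epochs past `min_epoch`) with a warning.

## Evaluation

* `select_max_accuracy()`: highest contralateral test accuracy among epochs
  > 50 with train loss < 0.05 ("nearly zero", "after epoch 50"); both
  configurable; ties resolve to the earliest epoch.
* Accuracy is **segment-level** (matching the 696-segment counting); a
  patient-level majority vote would be a labeled extension, not the default.
* `loss_ratio_sweep()` re-trains with identical seeds per ratio so the
  weighting is the only difference.
* `roc_auc()` sweeps thresholds over the contralateral head's probability
  of a good response (the head the stated test objective scores) and equals
  pairwise concordance with ties at 1/2 — asserted exactly against a
  brute-force oracle.
* `stability()` is the population SD of contralateral test accuracy over
  the final epochs (the instability the single-task runs display late in
  training is the motivation for the multitask design).
* `pearson_r()` reports two-sided p-values from the t-transform; no
  multiple-testing correction is applied (none was in the source analysis).

Two ambiguities were decided as follows: the DBS on/off ratio at 6 months
is the endpoint (the post-operative-over-pre-operative alternative that
appears in some summaries is available via
`attach_labels(ratio_type = "post_pre")`); and a patient's response *group*
for test-set stratification uses the contralateral label, since
distinguishing the contralateral outcome is the stated test objective.

## Desk-scale testing and budgets

The acceptance suite trains 25 models (3 bands × 5 seeds at 5:1, plus 5
matched-seed 1:1 runs and 5 single-task runs) on a fixed 40-patient cohort
with the effect injected into the 50–500 Hz band. To fit a 1-CPU budget the
cohort uses 1-s segments at 12 kHz and ~6 segments per patient; the
generator's statistical structure (couplings, noise, calibration, 2+2 test
split) is unchanged. Chance-level behavior is verified on `effect_size = 0`
cohorts, where mean test accuracy must sit in 0.5 ± 0.1.

## Known limitations

* The tiny trunk is a stand-in: absolute accuracies are not comparable to
  the published full-VGG16 numbers, and the real-data results (80.21% max
  accuracy, AUC 0.88, the reported correlation coefficients) are not
  reproducible because the patient data are not deposited — the pipeline
  reproduces the *procedures* and their qualitative behavior on synthetic
  cohorts.
* Band confinement is approximate (wavelet bandwidth, edge splatter), so
  "null" bands can retain faint outcome information on short segments.
* The affine latent-feature model is the simplest structure producing
  tunable class separation and bilateral correlation; it makes no claim of
  biophysical realism.
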