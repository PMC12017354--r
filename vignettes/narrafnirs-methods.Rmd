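---
title: "Linking narrative word use to event-locked prefrontal fNIRS activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking narrative word use to event-locked prefrontal fNIRS activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narrafnirs)
```

## The analysis problem

`narrafnirs` implements a multimodal analysis that links the words a
speaker uses while narrating a traumatic experience to the hemodynamic
response of prefrontal cortex measured by functional near-infrared
spectroscopy (fNIRS). The study design it supports compares two groups
— participants with PTSD and trauma-exposed controls (TEC) — over a
540 s protocol: 300 s of quiet rest, 30 s of digit recitation, 180 s of
impromptu trauma narration, and a second 30 s digit block. A 48-channel
optical montage samples two wavelengths (730/850 nm) at 11 Hz; the
narration is transcribed with per-word onset times, and each use of a
negative emotional word becomes an event marker for the fNIRS analysis.

Because the corresponding human recordings are not public, the package
pairs the analysis pipeline with a first-class synthetic cohort
generator. Every pipeline stage is exercised end to end on simulated
cohorts whose statistical structure mirrors the reported group effects,
so correctness claims about the pipeline are testable without any
download.

## Pipeline

1. **Optical preprocessing** (`preprocess_recording`): motion-artifact
   correction in optical-density space (running-median deviation
   detection with cubic-spline interpolation), inversion of the
   modified Beer–Lambert law to oxy-/deoxyhemoglobin concentration
   changes, cubic polynomial detrending, a zero-phase 0.01–0.20 Hz
   band-pass, and rest-referenced z-scoring (each channel transformed
   by the mean and SD of its 300 s resting baseline).
2. **Language features** (`tag_tokens_lexicon`, `honore_r`,
   `emotion_rates`): tokens are labelled by a category lexicon
   (negative / positive / factual / neutral); per-narrative outputs are
   the emotion-category rates (percent of tokens) and Honoré's R
   (`100·ln N / (1 − V1/V)`, natural log) as the lexical-richness
   statistic.
3. **Prosody features** (`mean_pitch`, `semitone_change`,
   `count_pauses`): voiced-frame mean f0; pitch declination as
   `12·log2` of the ratio of the last to the first voiced-decile median
   f0; pauses as maximal unvoiced runs of at least 60 ms (closed
   threshold).
4. **Neural tagger** (`train_tagger`, `forward_tagger`,
   `encode_document`): a hierarchical bidirectional RNN with Elman
   (tanh) cells and two parallel per-token softmax heads (emotional vs
   not, factual vs not); sentence vectors are concatenated final
   forward/backward states, consumed by an upper-level recurrent cell.
   Trained by full-batch gradient descent on the summed cross-entropy
   of both heads, with analytic gradients (verified against finite
   differences in the test suite).
5. **Event-locked analysis** (`extract_windows`, `subject_activation`,
   `group_channel_test`, `grand_average`, `characterize_timecourse`):
   10 s windows of z-scored Oxy-Hb after each negative-word onset;
   per-subject, per-channel activation as the pooled window mean minus
   the pooled mean of the two digit blocks; channelwise two-sided
   Mann–Whitney U tests with Benjamini–Hochberg FDR adjustment and
   Cliff's delta; group-average time courses (within-subject mean over
   events, then unweighted mean over subjects) characterized by
   latency, slope, peak, peak-minus-minimum difference, and a Spearman
   rank correlation against time.
6. **Group statistics** (`auto_compare`, `gated_correlation`,
   `ci_mean`, `required_n`): Shapiro–Wilk-gated t vs Mann–Whitney
   comparisons (chi-square for categorical variables) with
   |Cohen's d| / |Cliff's delta| / |Cohen's h| effect sizes,
   normality-gated Pearson/Spearman correlation, exact noncentral-t
   a priori power computation, and t-based confidence intervals from
   summary statistics.

## Design choices in the pipeline

Several steps are named but not fully specified by the protocol the
package follows; the package's choices are:

* **Stage order.** Motion correction operates in OD space (artifacts
  are optical), Beer–Lambert inversion precedes filtering (so the
  filter acts linearly on concentrations), and z-scoring is last.
  Double z-scoring is an error, not a silent no-op.
* **Filter realization.** The band-pass is a cascade of an order-3
  Butterworth low-pass and an order-3 high-pass, each applied forward
  and backward (zero phase). The low-pass runs first with
  even-reflection padding so that strong out-of-band oscillations
  (cardiac) are removed before the high-pass's long odd-reflection
  padding; a cubic polynomial detrend precedes filtering. This keeps
  filter edge transients out of the resting baseline and the trailing
  digit block, which the activation measure uses as its control
  condition. Passband amplitude is preserved within 1% at 0.05 Hz and
  a 1.1 Hz probe is attenuated by more than 60 dB.
* **Extinction coefficients.** A standard compiled extinction table at
  730/850 nm (HbO 0.390/1.058, HbR 1.102/0.691 cm⁻¹ mM⁻¹), DPF 6.0,
  3 cm source–detector separation; all configurable in
  `mbll_constants()`.
* **Latency rule.** "Began to rise significantly" is operationalized
  as the first time the group-average curve stays above
  `baseline mean + 2·SD` (baseline = first 2 s of the window) for at
  least 1 s; the profile is flagged "no latency" when that criterion
  is met at t = 0 or never. The *difference* statistic is peak minus
  window minimum, the only reading consistent with a peak of 0.184
  coexisting with a difference of 0.273; a `difference = "baseline"`
  switch is provided.
* **Slope units.** The slope is reported both per sample and per
  second; at 11 Hz a per-sample slope of ~0.0067 over a ~3.7 s rise
  matches a peak-minus-minimum difference of ~0.27, so the per-sample
  convention is treated as primary.
* **Small-sample tests.** `group_channel_test` uses exact Mann–Whitney
  enumeration when both groups have at most 8 subjects (and no ties)
  and the tie-corrected normal approximation with continuity
  correction otherwise. The normality gate applies Shapiro–Wilk to
  each group at α = 0.05; if either group fails, the nonparametric
  test is used. t tests use the Welch variant.

## The synthetic cohort

`cohort_spec()` defines the study conditions; its defaults are the
reported ones: 35 PTSD-like and 37 TEC subjects; negative-word rates
5.89% (SD 3.00) vs 4.21% (SD 2.83) of tokens; lexical-richness targets
30.23 vs 34.59 (see below); pitch 201.21 (32.84) vs 180.47 (43.91) Hz;
semitone change −15.11 (6.53) vs −17.10 (6.59); pause counts 385.09
(118.34) vs 362.60 (316.22); CAPS-5 totals 50.89 (7.57) with an
inclusion floor of 45; a criterion-D correlation target of 0.349; and
event-locked hemodynamics with landmarks at 3.82 s (rise onset),
7.55 s (peak) and 12 s (return) for controls versus a latency-free
sustained response for the PTSD-like group. Windowed activation
targets are 0.153 (PTSD) and 0.047 (TEC) in rest-referenced z-units.

Notable generator decisions:

* **Mean-calibrated truncated draws.** Several reported distributions
  carry hard floors (CAPS-5 ≥ 45, rates ≥ 0). Truncating a normal at
  the floor would shift its mean upward, so draws use a truncated
  normal whose location is solved numerically so the *post-truncation*
  mean equals the reported mean. (No truncated normal with a floor of
  45 can have mean 50.89 *and* SD 7.57 — the maximum attainable SD at
  that mean gap is ≈5.9 — so the printed SD is treated as the
  pre-truncation scale.)
* **Lexical richness scale.** The canonical Honoré statistic is
  bounded below by `100·ln N` (≈611 for a 450-token narrative), so
  printed group values near 30 cannot be canonical-scale values; the
  generator interprets them on an R/100 scale and tunes the expected
  hapax fraction accordingly (`1 − V1/V ≈ ln N / target`), solving a
  closed-form expected-type-count equation for the fraction of tokens
  drawn as fresh rare words versus Zipf-weighted category cores. The
  packaged lexicon covers the entire generator vocabulary, so lexicon
  tagging is exact on synthetic data.
* **Speech timing.** 2.5 tokens/s with jittered, strictly increasing
  onsets; prosody tracks at 100 frames/s realize the drawn pitch mean
  exactly, span the drawn semitone change so that the decile-median
  estimator recovers it (the deciles sit ~5% from each end, so the
  generated span is widened by 1/0.9), and place the drawn number of
  60–200 ms unvoiced gaps.
* **Hemodynamic shapes.** Control responses are piecewise linear
  through the three landmarks (the protocol reports landmarks, not a
  parametric HRF). The PTSD-like response is a narration-long tonic
  plateau plus sustained event bumps that begin 2 s *before* each
  negative word (pre-articulatory arousal during speech planning),
  ramp over 1.5 s, and persist ~16 s with a slow vasomotor-style
  fluctuation (depth 0.6, period 7 s). This realizes "elevated with no
  apparent latency": the response is already up when the word is
  spoken, the event-locked average fluctuates without a time trend,
  and the latency detector's baseline inherits enough structure that
  no spurious onset is found.
* **Amplitude calibration.** Concentration amplitudes are calibrated
  deterministically — never per seed — so the pipeline's windowed,
  digit-baseline-subtracted group means land at the z-unit targets:
  a single filtered response template gives the own-event gain, the
  expected overlap from other events enters as the event rate times
  the narration boxcar convolved with the response shape (which also
  leaks into the trailing digit block), and the generated noise mix is
  propagated analytically to an expected rest SD. Monte-Carlo checks
  put this calibration within ~2% for the control shape and ~1% for
  the sustained shape at fixed event rates; with subject-level rate
  heterogeneity, recovered group means sit within ~10% of targets.
* **Noise model.** Per-channel optical noise comprises thermal-scale
  drift (0.0012/0.0028 Hz), cardiac (1.1 Hz) and respiratory (0.25 Hz)
  oscillations, a white instrument floor, optional motion spikes
  (default off; enabled in tests of the motion stage), and a
  spontaneous low-frequency oscillation in the Mayer-wave band
  (0.085–0.115 Hz, per-channel frequency and phase) whose amplitude is
  suppressed to 5% during the task segments. The task-state dependence
  is deliberate: the reported between-subject SDs (0.084/0.026 for
  windowed means over ~19–26 events) imply task-epoch noise of roughly
  a quarter of the resting SD used for z-scoring, which no stationary
  noise model can produce, while task-related suppression of
  spontaneous oscillations is a documented phenomenon. Amplitudes were
  chosen so that the pipeline-measured subject-level activation SDs
  land near the reported ones.

## What passing tests do and do not show

The synthetic cohort emulates the *reported statistics* — group rates,
prosody distributions, event-locked shapes, activation levels and
their spread — under idealized conditions: linear superposition of
responses, stationary sinusoidal physiology, exact lexicon coverage,
and uniform speech rate. It does not emulate real optical coupling
variation, serial correlation between word use and physiology,
Mandarin segmentation ambiguity, or speech-recognition timing error.
Tests passing on this cohort certify that the pipeline recovers known
structure at realistic sizes and noise levels; they do not certify
performance on any particular real recording system.

Two statistics remain genuinely volatile at the study size (35/37
subjects, ~19–26 events each). The grand-average curve carries
irreducible per-sample noise of ~0.01 z (the z-scale pins task noise),
so (a) the 2-SD latency rule scatters by a few hundred ms around the
3.82 s landmark and occasionally triggers early on a noise excursion,
and (b) the Spearman trend statistic of the (flat) PTSD-like profile
has a null spread of ~0.1–0.15. Replicate-level checks therefore
target the FDR-corrected group contrast (stable across all seeds
tested), while the time-course profile checks are anchored to the
reference cohort.

## Problem sizes used in the test suite

Unit tests run on cohorts of 2–6 subjects and on constructed fixtures;
the replicate-level acceptance checks run 20 full cohorts at the
default 35 + 37 size plus the reference cohort; lexical-rate recovery
uses 500 synthetic narratives. These sizes put every statistic's
Monte-Carlo error well inside the asserted tolerances while keeping
the suite's total runtime modest.

## Known limitations

* The neural tagger can only classify words it has seen; synthetic
  narratives are deliberately hapax-rich, so tagger/lexicon agreement
  is evaluated over in-vocabulary tokens, and the lexicon path is the
  default source of event markers.
* Deoxyhemoglobin is simulated as a fixed negative fraction (−0.3) of
  the Oxy-Hb response and is preprocessed but not analyzed further.
* The 808 nm reference wavelength of the acquisition system is not
  simulated; the analysis uses the two primary wavelengths.
* Channel-to-region assignment is a fixed montage convention (the
  target channel sits over the left anterior medial prefrontal
  cortex); no cortical registration is performed.
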