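---
title: "Detecting probe-caught mind wandering from EEG complexity features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting probe-caught mind wandering from EEG complexity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwdetect)
```

## The problem

During a long, naturalistic task such as watching a lecture video, attention
periodically decouples from the task — *mind wandering* (MW). The
probe-caught method samples this state directly: the task is interrupted at
unpredictable moments by an on-screen *thought probe* asking where the
participant's attention was (1 = task content, 2 = task-related thoughts,
3 = unrelated thoughts), how confident they are in that answer (1–3), and how
drowsy they feel (1–4). Response 3 labels the moments before the probe as MW;
responses 1 and 2 as non-MW; probes answered with the lowest confidence are
excluded outright. The detection question is then a within-participant
two-class problem: can the EEG in a short window before a probe predict the
upcoming report?

`mwdetect` implements this analysis end to end — signal conditioning, window
extraction, feature computation, and leakage-safe evaluation — together with
a synthetic cohort generator, so every stage is testable without access to
any recording.

## Signal conditioning

The pipeline order is fixed: band-pass 1–40 Hz, common average reference,
downsample to 256 Hz, then marking of abrupt high-amplitude segments.

* **Filtering.** Zero-phase FIR (Hamming design). The order is chosen from a
  transition width of 25% of each cutoff (`order ≈ 3.3 fs / Δf`), capped for
  short inputs; the symmetric kernel is applied by FFT convolution with exact
  group-delay compensation, which is algebraically identical to zero-phase
  filtering for a linear-phase kernel and much faster than forward–backward
  filtering at the ~13 000-tap orders a 1 Hz cutoff implies at 1024 Hz.
* **Segment rejection.** Calibration-based artifact-subspace methods are used
  in this design only to *delete* bad stretches, so the package implements
  exactly that contract: a sliding 1 s RMS (0.5 s step) per channel,
  robust z-scores against the median/MAD of all window RMS values, and any
  window exceeding `z = 8` in any channel is added to `rejected_intervals`.
  The threshold is in robust-z units — there is no derivable mapping from
  subspace-method cutoffs to these units, so the default was calibrated on
  synthetic data: clean colored-noise sessions produce zero rejections at
  `z = 8`, while a 500 µV burst is always caught.
* **Ocular activity.** Horizontal-EOG regression
  (`regress_out_heog()`) is provided as an optional linear stand-in for
  component-based eye-artifact removal; the default pipeline leaves ocular
  activity in, which mirrors the finding that eye signals can carry
  MW-relevant information.

## Windows and augmentation

All windows are 10 s (2560 samples at 256 Hz), snapped to the nearest
sample. Training windows are class-dependent: MW probes contribute 4 windows
ending at `t − k·2.5 s` (k = 0..3, 75% overlap), non-MW probes 2 windows
ending at `t − k·5 s` (k = 0..1, 50% overlap), so the earliest onsets are
17.5 s and 15 s before the probe. This denser sampling of the rarer class
(the MW base rate is ~28%) narrows the class imbalance before any synthetic
balancing: with rates 4:2 the window-level MW fraction rises from 0.28
towards 0.44. Evaluation always uses the single window `[t − 10, t]`,
regardless of class.

Windows overlapping a rejected interval, the block boundary, or the session
edge are dropped (conservative rule; the alternative — truncating or
shifting windows — would mix feature supports). Participants whose MW probe
proportion is below 10% after confidence exclusion are removed; a
proportion of exactly 10% is kept, reading "below" strictly.

## Feature families

Seven per-channel families are computed from each window:

* **Multiscale entropies** (MSE, MPE, MDE): the series is coarse-grained by
  averaging s consecutive samples (s = 1..14; analyses restrict to 1..10,
  where detection is known to be strongest), and a mono-scale metric is
  applied per scale — sample entropy (m = 2, r = 0.2 SD, Chebyshev matching
  without self-matches, nats), permutation entropy (m = 3, τ = 1, ties
  broken by temporal order, normalized bits), and dispersion entropy
  (m = 2, c = 6 classes via the normal CDF, nats). These defaults follow the
  metrics' original publications, as the upstream parameter settings are not
  published; all are overridable through `complexity_params()`.
* **Fractal dimensions**: Higuchi (k_max = 10) and Katz. Katz uses the
  original waveform geometry — path length through the points `(i, x_i)` —
  under which straight lines give exactly 1. (A popular simplified variant
  using amplitude-only path length is scale-invariant but degenerates on
  sawtooth series; the original formulation is used here.)
* **DFA**: the mean-removed series is integrated, order-1 polynomials are
  fitted in non-overlapping boxes (10 log-spaced sizes from 16 to N/4), and
  the scaling exponent is the log–log slope of the RMS residual. White noise
  recovers α ≈ 0.5, integrated noise α ≈ 1.5.
* **Band power**: a 5-level Daubechies-4 DWT (orthonormal periodic pyramid,
  implemented in-package) at 256 Hz; each band signal is reconstructed from
  its coefficient set alone and its mean squared amplitude taken. The dyadic
  bands approximate the canonical ones — A5 (0–4 Hz) → delta, D5 (4–8) →
  theta, D4 (8–16) → alpha, D3 (16–32) → beta. The printed band edges
  (8–12, 12–30 Hz) cannot coincide with dyadic splits; reconstruction was
  chosen over raw coefficient energies for unit consistency (µV²). Note the
  Daubechies-4 filters roll off gently, so a 10 Hz tone leaves ~15% of its
  energy in the neighboring theta band — the band mapping is recorded in
  every feature descriptor.

Feature dimensions are as described: 14 scales × 30 channels = 420 per
multiscale family, 4 × 30 = 120 for band power, 30 for each
one-number-per-channel family; the pooled set at scales 1–10 has
3×300 + 120 + 3×30 = 1110 columns. Undefined values (sample entropy with no
matching templates, over-coarse scales) are stored as missing; epochs with
more than 20% missing features are dropped, and remaining gaps are
median-imputed *inside training folds only*.

## Evaluation

Cross-validation is probe-grouped: folds partition *probes*, never windows,
so overlapping windows of one probe can never straddle train and test. Per
participant and repeat (2 repeats × 10 label-stratified folds), training
uses every augmentation window of the training probes and testing scores the
single pre-probe window of each held-out probe. Inside each training fold,
in order: median imputation, SMOTE balancing (synthetic minority samples
interpolated between minority neighbors, originals untouched), optional
MRMR selection, then a probability random forest (`ranger`, library
defaults, impurity importance). Balancing precedes selection — the upstream
description presents augmentation/balancing as part of dataset
construction, selection as part of modeling — and both are fitted strictly
on training data.

MRMR uses the MID (difference) criterion — greedy maximization of
`MI(f; y) − mean MI(f; selected)` — with mutual information estimated on
8-bin equal-frequency discretizations; the variant, estimator and bin count
are not published upstream, so these defaults are the package's own and are
recorded in the run manifest.

Per participant and repeat, out-of-fold scores are pooled and summarized as
a rank-based (Mann–Whitney) AUC; repeats are averaged. The report also
collects per-scale and per-channel AUC curves, mean impurity importance per
channel, and the mutual information between the binarized predictions of
different feature families.

### A note on pooled CV AUC at small probe counts

Pooling out-of-fold scores across folds gives a *pessimistically biased*
AUC when the per-participant probe count is small: removing a held-out MW
probe from a ~16-probe training set shifts the training composition against
its own class. In a label-independent mechanics simulation this bias is
substantial at 16 probes per participant (mean AUC ≈ 0.38) and gone by 32
probes (≈ 0.50–0.53). The simulation-based tests therefore generate about
30–35 labeled probes per participant — comfortably in the unbiased regime
and in line with full-length recording sessions (~80 probes).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis relies
on, not the biophysics:

* **Probe schedules**: per block, random probes at uniform 40–120 s
  intervals plus up to 5 manually triggered probes; any probe within 20 s of
  the previous is skipped. Each probe carries a latent attentional state
  drawn at the configured MW rate (default 0.28); the response is 3 exactly
  when the state is MW. Confidence responses include a small (5%)
  lowest-confidence mass so the exclusion rule is exercised.
* **Background activity**: 1/f^β colored noise per channel plus a shared
  volume-conduction component (mixing weight 0.3), scaled to 10 µV SD.
  Within 20 s before each MW probe (and 2 s after, so crossfade ramps stay
  outside all analysis windows) the spectral exponent switches from 1.0 to
  1.3. Critically, both regimes are rendered from the *same* white-noise
  phases under different spectral shapings: with equal exponents the signal
  is bit-identical, making the null model exactly label-independent. (An
  earlier design drew an independent realization for the MW regime; grouped
  CV then detected the realization's finite-sample spectral fingerprint
  even under the null — a useful cautionary tale for synthetic benchmarks.)
* **Alpha bursts**: a 10 Hz carrier under a slow (< 0.8 Hz) non-negative
  random envelope, posterior-weighted, 5 µV in the on-task state and 8 µV in
  the MW state (alpha power tends to rise as attention decouples).
* **Ocular transients**: 0.4 s raised-cosine deflections (~75 µV, mostly
  positive) at 2/min, frontally weighted, with a signed HEOG trace.
* **Seeds**: one cohort seed; per-participant streams derived by an integer
  hash, so cohorts are reproducible and participants independent.

What the generator does *not* emulate: volume-conducted source geometry,
drowsiness-dependent dynamics, non-stationary artifact regimes, or any
specific effect size — the upstream work does not characterize MW/non-MW
EEG effect sizes, so the state effect here (Δβ = 0.3, Δalpha = 3 µV) is a
free, fixed choice. Passing recovery tests therefore demonstrates that the
pipeline detects a planted effect of plausible form and is unbiased in its
absence; it says nothing about absolute detectability in real recordings.

## Problem sizes used by the tests and acceptance script

Full-scale sessions (30 channels, 1024 Hz, 5 × 1080 s) are ~1.3 GB of
samples each; the package handles them, but the simulation-based checks run
on scaled cohorts chosen once: 8 channels (FP1, FP2, F3, F4, C3, C4, O1,
O2), 256 Hz generation rate, 4 × 600 s blocks, 20 participants for
recovery runs — about 40–45 labeled probes per participant, of which
roughly three quarters keep a clean evaluation window after segment
rejection, leaving the ~33 scorable probes needed for unbiased pooled CV
AUC (see above). Recovery evaluation
uses the MPE (scales 1–3), band-power and Katz families pooled, with 20
features selected by MRMR per fold.

## Known limitations

* The segment-rejection stand-in deletes whole windows; it does not attempt
  subspace reconstruction, channel interpolation, or component-based
  cleaning.
* Dyadic wavelet bands only approximate the printed alpha/beta edges.
* Sample entropy is O(N²) per series; at the default epoch length this is
  the slowest feature family by a wide margin, which is why scaled
  simulations prefer the O(N) families.
* Between-participant (transfer) models, forest hyperparameter tuning and
  repeated-measures inference on real cohorts are out of scope.
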