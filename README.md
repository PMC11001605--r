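# mwdetect

Detection of probe-caught **mind wandering** (MW) from multichannel EEG,
for researchers studying attention during naturalistic tasks and for
methodologists who need a leakage-safe reference pipeline for
probe-grouped EEG classification.

During a task, on-screen thought probes ask where the participant's
attention was (response 3 = off-task → MW, 1/2 = on-task; lowest-confidence
answers excluded). The package asks whether the 10 s of EEG before each
probe predicts the report, using seven per-channel feature families:

- **Multiscale entropies** — sample entropy (−ln A/B over matched templates,
  m = 2, r = 0.2·SD), permutation entropy (Shannon entropy of ordinal
  patterns, m = 3, τ = 1), dispersion entropy (normal-CDF symbolization,
  c = 6, m = 2), each on coarse-grained series at scales s = 1..14;
- **Temporal dimensionality** — Higuchi and Katz fractal dimensions,
  detrended fluctuation analysis (Hurst-type exponent α);
- **Band power** — 5-level Daubechies-4 wavelet decomposition with dyadic
  bands mapped to delta/theta/alpha/beta.

Evaluation is **leave-probes-out**: 2 × 10-fold stratified cross-validation
whose folds partition probes, never windows, so the overlapping training
windows of one probe (4 per MW probe at 2.5 s steps, 2 per non-MW probe at
5 s steps) can never straddle train and test. Inside each training fold:
median imputation → SMOTE balancing → optional MRMR feature selection
(MID criterion, 8-bin equal-frequency MI) → probability random forest;
test probes are scored on the single window ending at the probe and
summarized as rank-based AUC, with per-channel impurity importance and
between-family prediction mutual information.

A synthetic cohort generator (`generate_cohort()`) emulates the probe
schedule (40–120 s random intervals, ≤5 manual probes/block, 20 s minimum
gap, 28% MW rate) and a state-dependent signal model (1/f^β background with
β switching 1.0 → 1.3 and alpha bursts 5 → 8 µV inside the 20 s before MW
probes), so the full pipeline is testable without any recordings.

## Worked example

```r
library(mwdetect)

spec <- cohort_spec(n_participants = 3, n_blocks = 2, block_duration = 450,
                    sampling_rate = 256, n_channels = 8,
                    channel_labels = c("FP1","FP2","F3","F4","C3","C4","O1","O2"),
                    seed = 42)
cohort <- generate_cohort(spec, signal_model())
cohort[["S01"]]
#> <mw_session S01> 8 ch x 230400 samples @ 256 Hz (15.0 min), 13 probes

report <- run_experiment(
  cohort, params = complexity_params(scales = 1:2),
  cv = cv_config(seed = 7),
  families = c("BP", "KFD"), scales_analysis = 1:2,
  mrmr_sweep_k = 10, analyses = c("family", "mrmr", "prediction_mi"))
report
#> <mw_eval_report> 2 participants (1 excluded below the MW-proportion threshold)
#> mean AUC by family:
#>   BP   1.000
#>   KFD  1.000
#> pooled-feature AUC by MRMR feature count:
#>   k=10   1.000

round(report$prediction_mi, 3)
#>        BP   KFD
#> BP  0.837 0.837
#> KFD 0.837 0.837
```

One of the three participants reported MW at fewer than 10% of probes and
is excluded by the participant filter. The default `signal_model()` plants a
deliberately strong state effect (spectral-slope and alpha-amplitude
changes before MW probes), so both feature families separate the classes
perfectly at this toy scale; `null_signal_model()` removes the effect and
drives AUC to chance. The prediction-MI matrix reports how similar the
binarized predictions of the two family classifiers are (diagonal = the
entropy of each prediction vector).

`write_report(report, dir)` writes the AUC tables, importance maps, MI
matrix and a JSON manifest with the full configuration.

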