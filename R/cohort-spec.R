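#' Standard 30-channel 10-20 montage labels
#'
#' The electrode set of a 30-channel scalp recording (10-20 system,
#' frontal-polar through occipital).
#'
#' @param n number of leading labels to return (default all 30).
#' @return character vector of channel labels.
#' @export
montage_30 <- function(n = 30) {
  labs <- c("FP1", "FP2", "F11", "F7", "F3", "FZ", "F4", "F8", "F12",
            "FT11", "FC3", "FCZ", "FC4", "FT12", "T7", "C3", "CZ", "C4",
            "T8", "CP3", "CPZ", "CP4", "P7", "P3", "PZ", "P4", "P8",
            "O1", "OZ", "O2")
  if (n > length(labs)) stop("montage has only 30 labels")
  labs[seq_len(n)]
}

#' Specification of a synthetic EEG cohort
#'
#' Describes the recording and probe-schedule conditions of a probe-caught
#' mind-wandering study: multi-block continuous EEG with on-screen thought
#' probes at random 40-120 s intervals plus a capped number of manually
#' triggered probes, and the marginal rate at which probes are answered
#' "off-task" (mind wandering, MW).
#'
#' @param n_participants number of participants.
#' @param n_blocks experimental blocks per session (default 5).
#' @param block_duration block length in seconds (default 1080).
#' @param sampling_rate sampling rate in Hz (default 1024).
#' @param n_channels number of scalp channels (default 30).
#' @param channel_labels channel names; default the leading `n_channels`
#'   labels of [montage_30()].
#' @param probe_interval_range min/max seconds between scheduled random
#'   probes (default `c(40, 120)`).
#' @param min_probe_gap probes closer than this to the previous probe are
#'   skipped (seconds, default 20).
#' @param manual_probe_cap_per_block maximum manually triggered probes per
#'   block (default 5).
#' @param mw_rate probability that a probe catches mind wandering
#'   (default 0.28).
#' @param confidence_distribution probabilities of confidence responses
#'   1, 2, 3 (default `c(0.05, 0.35, 0.60)`; the small confidence-1 mass
#'   exercises the exclusion rule).
#' @param drowsiness_distribution probabilities of drowsiness responses 1-4.
#' @param seed master cohort seed; per-participant streams are derived from
#'   it with [derive_seed()].
#' @return an object of class `mw_cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        n_blocks = 5,
                        block_duration = 1080,
                        sampling_rate = 1024,
                        n_channels = 30,
                        channel_labels = montage_30(n_channels),
                        probe_interval_range = c(40, 120),
                        min_probe_gap = 20,
                        manual_probe_cap_per_block = 5,
                        mw_rate = 0.28,
                        confidence_distribution = c(0.05, 0.35, 0.60),
                        drowsiness_distribution = c(0.05, 0.15, 0.30, 0.50),
                        seed = 1L) {
  stopifnot(n_participants >= 1, n_blocks >= 1, block_duration > 0,
            sampling_rate > 0, n_channels >= 1)
  if (length(channel_labels) != n_channels || anyDuplicated(channel_labels))
    stop("channel_labels must be unique and of length n_channels")
  if (length(probe_interval_range) != 2 ||
      probe_interval_range[1] > probe_interval_range[2])
    stop("probe_interval_range must be an increasing pair of seconds")
  if (probe_interval_range[1] < min_probe_gap)
    stop("probe_interval_range low bound must be >= min_probe_gap")
  if (mw_rate <= 0 || mw_rate >= 1) stop("mw_rate must lie in (0, 1)")
  stopifnot(length(confidence_distribution) == 3,
            all(confidence_distribution >= 0),
            abs(sum(confidence_distribution) - 1) < 1e-8,
            length(drowsiness_distribution) == 4)
  structure(list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    block_duration = block_duration,
    sampling_rate = sampling_rate,
    n_channels = as.integer(n_channels),
    channel_labels = channel_labels,
    probe_interval_range = probe_interval_range,
    min_probe_gap = min_probe_gap,
    manual_probe_cap_per_block = as.integer(manual_probe_cap_per_block),
    mw_rate = mw_rate,
    confidence_distribution = confidence_distribution,
    drowsiness_distribution = drowsiness_distribution,
    seed = as.integer(seed)
  ), class = "mw_cohort_spec")
}

#' Generative model of the synthetic EEG signal
#'
#' Parameterizes the statistical structure the downstream analysis assumes:
#' 1/f^beta background activity whose exponent (and alpha-band amplitude)
#' differs between mind-wandering and on-task states inside a short window
#' before each probe, plus waxing-waning alpha bursts, weak fixed band
#' oscillations, and low-frequency high-amplitude ocular transients weighted
#' toward the frontal-polar channels.
#'
#' @param background_exponent_nonmw spectral slope beta of on-task background
#'   activity (default 1.0).
#' @param background_exponent_mw beta inside the pre-probe effect window of
#'   mind-wandering probes (default 1.3).
#' @param alpha_burst_amp_nonmw,alpha_burst_amp_mw alpha burst amplitude in
#'   microvolts for the two states (defaults 5 and 8; alpha power tends to
#'   rise when attention decouples from the task).
#' @param alpha_freq alpha center frequency in Hz (default 10).
#' @param band_osc_amps named amplitudes (microvolts) of fixed narrow-band
#'   oscillations added in both states.
#' @param ocular_artifact_rate ocular transients per minute in frontal
#'   channels (default 2).
#' @param ocular_amp peak amplitude of an ocular transient in microvolts.
#' @param noise_sd standard deviation of the background activity in
#'   microvolts (default 10).
#' @param shared_noise_frac mixing weight of a common volume-conduction
#'   component shared across channels (default 0.3).
#' @param effect_window seconds before a mind-wandering probe in which the
#'   MW signal parameters apply (default 20; must cover the longest analysis
#'   window of 17.5 s).
#' @return an object of class `mw_signal_model`.
#' @export
signal_model <- function(background_exponent_nonmw = 1.0,
                         background_exponent_mw = 1.3,
                         alpha_burst_amp_nonmw = 5,
                         alpha_burst_amp_mw = 8,
                         alpha_freq = 10,
                         band_osc_amps = c(delta = 2, theta = 2, beta = 1),
                         ocular_artifact_rate = 2,
                         ocular_amp = 75,
                         noise_sd = 10,
                         shared_noise_frac = 0.3,
                         effect_window = 20) {
  stopifnot(background_exponent_nonmw >= 0, background_exponent_mw >= 0,
            alpha_burst_amp_nonmw >= 0, alpha_burst_amp_mw >= 0,
            alpha_freq > 0, all(band_osc_amps >= 0),
            ocular_artifact_rate >= 0, ocular_amp >= 0, noise_sd >= 0,
            shared_noise_frac >= 0, shared_noise_frac <= 1)
  if (effect_window < 17.5)
    stop("effect_window must cover the longest analysis window (17.5 s)")
  structure(list(
    background_exponent_nonmw = background_exponent_nonmw,
    background_exponent_mw = background_exponent_mw,
    alpha_burst_amp_nonmw = alpha_burst_amp_nonmw,
    alpha_burst_amp_mw = alpha_burst_amp_mw,
    alpha_freq = alpha_freq,
    band_osc_amps = band_osc_amps,
    ocular_artifact_rate = ocular_artifact_rate,
    ocular_amp = ocular_amp,
    noise_sd = noise_sd,
    shared_noise_frac = shared_noise_frac,
    effect_window = effect_window
  ), class = "mw_signal_model")
}

#' Null-effect signal model
#'
#' A [signal_model()] whose mind-wandering parameters equal the on-task
#' parameters, so probe labels carry no signal information. Used as the
#' negative control in parameter-recovery simulations.
#'
#' @param ... overrides passed to [signal_model()].
#' @export
null_signal_model <- function(...) {
  m <- signal_model(...)
  m$background_exponent_mw <- m$background_exponent_nonmw
  m$alpha_burst_amp_mw <- m$alpha_burst_amp_nonmw
  m
}
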