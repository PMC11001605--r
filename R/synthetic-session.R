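# Synthetic probe-caught EEG sessions: probe schedules with ground-truth
# attentional state, 1/f background activity with state-dependent spectral
# slope and alpha amplitude, ocular transients, and a shared volume-conduction
# component.

# Spectrally shape a white-noise Fourier transform into unit-variance
# 1/f^beta noise. Keeping the white-noise phases fixed lets the same
# realization be rendered under different exponents, so a state-dependent
# slope change alters only the spectrum, never the underlying realization.
shape_noise <- function(W, fs, beta) {
  n <- length(W)
  if (beta == 0) {
    x <- Re(stats::fft(W, inverse = TRUE)) / n
    return(x / stats::sd(x))
  }
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  sc <- ifelse(freq > 0, freq^(-beta / 2), 0)
  x <- Re(stats::fft(W * sc, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-variance 1/f^beta noise via FFT spectral shaping of white noise.
colored_noise <- function(n, fs, beta) {
  shape_noise(stats::fft(stats::rnorm(n)), fs, beta)
}

# Brick-wall FFT low-pass (used only to build slow random envelopes).
lowpass_fft <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  X[freq > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Map channel labels to relative weights by 10-20 region prefix.
prefix_weights <- function(labels, table, default) {
  w <- rep(default, length(labels))
  # longest prefixes first so FP/FT/FC take precedence over F
  for (p in names(table)[order(nchar(names(table)), decreasing = TRUE)]) {
    hit <- startsWith(toupper(labels), p) & w == default
    w[hit] <- table[[p]]
  }
  w
}

alpha_weights <- function(labels) {
  prefix_weights(labels,
                 c(O = 1, P = 0.8, CP = 0.6, C = 0.45, T = 0.45,
                   FC = 0.3, FT = 0.3, F = 0.25, FP = 0.15),
                 default = 0.4)
}

ocular_weights <- function(labels) {
  prefix_weights(labels,
                 c(FP = 1, F = 0.45, FC = 0.25, FT = 0.25, T = 0.1,
                   C = 0.1, CP = 0.05, P = 0.02, O = 0.01),
                 default = 0.1)
}

# Probe schedule for one block: random probes at uniform 40-120 s intervals,
# plus up to `cap` manually triggered probes; any probe within `min_gap`
# seconds of the previous retained probe is skipped.
schedule_block_probes <- function(duration, interval_range, min_gap, cap) {
  times <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::runif(1, interval_range[1], interval_range[2])
    if (t >= duration) break
    times <- c(times, t)
  }
  n_manual <- min(stats::rpois(1, 4), cap)
  manual <- sort(stats::runif(n_manual, min_gap, duration))
  tab <- rbind(data.frame(time = times,
                          trigger = rep("random", length(times))),
               data.frame(time = manual,
                          trigger = rep("manual", length(manual))))
  tab <- tab[order(tab$time), , drop = FALSE]
  keep <- logical(nrow(tab))
  last <- -Inf
  for (i in seq_len(nrow(tab))) {
    if (tab$time[i] - last >= min_gap) {
      keep[i] <- TRUE
      last <- tab$time[i]
    }
  }
  tab[keep, , drop = FALSE]
}

# 0.4 s raised-cosine transient used for blinks/saccade deflections.
ocular_pulse <- function(fs) {
  len <- max(3, round(0.4 * fs))
  0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
}

# Blend weight vector: 1 inside each [start, end) interval (sample units),
# with linear ramps of `ramp` samples just inside the edges.
blend_weights <- function(n, intervals, ramp) {
  w <- numeric(n)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1, intervals[i, 1])
    b <- min(n, intervals[i, 2])
    if (b <= a) next
    seg <- numeric(b - a + 1)
    seg[] <- 1
    r <- min(ramp, floor(length(seg) / 2))
    if (r > 0) {
      seg[seq_len(r)] <- seq_len(r) / r
      seg[length(seg) - seq_len(r) + 1] <- seq_len(r) / r
    }
    w[a:b] <- pmax(w[a:b], seg)
  }
  w
}

#' Generate one synthetic EEG session
#'
#' Produces a continuous multichannel recording with its probe event log.
#' Each probe carries a latent attentional state drawn at the cohort's MW
#' rate; the reported response is 3 for latent mind wandering and 1 or 2
#' otherwise, and signal parameters switch to the MW regime inside the
#' `effect_window` seconds preceding each MW probe.
#'
#' @param spec a [cohort_spec()].
#' @param model a [signal_model()].
#' @param participant_id identifier string (also seeds this participant's
#'   random stream via [derive_seed()]).
#' @return an object of class `mw_session`: list with `signal` (channels x
#'   samples matrix, microvolts), `sampling_rate`, `channel_labels`,
#'   `probes` (data.frame: probe_id, time_s, block, trigger, response,
#'   confidence, drowsiness, latent_mw), `blocks`, `heog`, `participant_id`,
#'   and `rejected_intervals` (NULL until artifact rejection).
#' @export
generate_session <- function(spec, model, participant_id) {
  stopifnot(inherits(spec, "mw_cohort_spec"), inherits(model, "mw_signal_model"))
  if (spec$block_duration <= spec$probe_interval_range[1])
    stop("block too short to hold at least one probe")
  fs <- spec$sampling_rate
  with_local_seed(derive_seed(spec$seed, participant_id), {
    nb <- spec$n_blocks
    n_blk <- round(spec$block_duration * fs)
    nch <- spec$n_channels
    sig <- matrix(0, nch, n_blk * nb)
    heog <- numeric(n_blk * nb)
    probes <- NULL
    w_alpha <- alpha_weights(spec$channel_labels)
    w_oc <- ocular_weights(spec$channel_labels)
    for (b in seq_len(nb)) {
      sched <- schedule_block_probes(spec$block_duration,
                                     spec$probe_interval_range,
                                     spec$min_probe_gap,
                                     spec$manual_probe_cap_per_block)
      np <- nrow(sched)
      latent <- stats::rbinom(np, 1, spec$mw_rate) == 1
      response <- ifelse(latent, 3L,
                         sample(c(1L, 2L), np, replace = TRUE,
                                prob = c(0.55, 0.45)))
      conf <- sample(1:3, np, replace = TRUE,
                     prob = spec$confidence_distribution)
      drow <- sample(1:4, np, replace = TRUE,
                     prob = spec$drowsiness_distribution)
      blk <- synth_block(n_blk, fs, model, w_alpha, w_oc,
                         mw_times = sched$time[latent])
      idx <- (b - 1) * n_blk + seq_len(n_blk)
      sig[, idx] <- blk$signal
      heog[idx] <- blk$heog
      if (np > 0) {
        probes <- rbind(probes, data.frame(
          probe_id = sprintf("%s_b%d_p%02d", participant_id, b, seq_len(np)),
          time_s = (b - 1) * spec$block_duration + sched$time,
          block = b,
          trigger = sched$trigger,
          response = response,
          confidence = conf,
          drowsiness = drow,
          latent_mw = latent,
          stringsAsFactors = FALSE))
      }
    }
    structure(list(
      signal = sig,
      sampling_rate = fs,
      channel_labels = spec$channel_labels,
      probes = probes,
      blocks = data.frame(block = seq_len(nb),
                          start_s = (seq_len(nb) - 1) * spec$block_duration,
                          end_s = seq_len(nb) * spec$block_duration),
      heog = heog,
      participant_id = participant_id,
      rejected_intervals = NULL,
      preproc = list()
    ), class = "mw_session")
  })
}

# One block of multichannel signal. `mw_times` are within-block probe times
# (seconds) whose preceding effect window uses the MW signal parameters.
synth_block <- function(n, fs, model, w_alpha, w_oc, mw_times) {
  nch <- length(w_alpha)
  # the MW regime persists ~2 s past the probe, so both crossfade ramps lie
  # outside every analysis window (windows span at most [t - 17.5, t])
  mw_iv <- if (length(mw_times)) {
    iv <- cbind(round((mw_times - model$effect_window) * fs) + 1,
                round((mw_times + 2) * fs))
    merge_intervals(iv)
  } else matrix(numeric(0), ncol = 2)
  w_mw <- blend_weights(n, mw_iv, ramp = round(0.5 * fs))

  # one white-noise realization per source, rendered under both exponents:
  # the MW regime re-shapes the same phases, so equal exponents give an
  # identical signal and the probe labels carry no realization fingerprint
  b_non <- model$background_exponent_nonmw
  b_mw <- model$background_exponent_mw
  two_regimes <- nrow(mw_iv) > 0 && b_mw != b_non
  W_shared <- stats::fft(stats::rnorm(n))
  shared <- shape_noise(W_shared, fs, b_non)
  shared_mw <- if (two_regimes) shape_noise(W_shared, fs, b_mw)
  mix <- model$shared_noise_frac

  # slow (<0.8 Hz) non-negative amplitude envelope for waxing/waning alpha
  env <- lowpass_fft(stats::rnorm(n), fs, 0.8)^2
  env <- env / mean(env)
  tt <- seq_len(n) / fs
  alpha_level <- model$alpha_burst_amp_nonmw +
    w_mw * (model$alpha_burst_amp_mw - model$alpha_burst_amp_nonmw)
  alpha_carrier <- sin(2 * pi * model$alpha_freq * tt + stats::runif(1, 0, 2 * pi))
  alpha_sig <- alpha_level * env * alpha_carrier

  osc <- numeric(n)
  osc_freqs <- c(delta = 2.5, theta = 6, beta = 20)
  for (bn in names(model$band_osc_amps)) {
    f0 <- osc_freqs[[bn]]
    if (is.null(f0)) next
    osc <- osc + model$band_osc_amps[[bn]] *
      sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
  }

  # frontal ocular transients (blinks mostly positive) + signed heog saccades
  pulse <- ocular_pulse(fs)
  n_ev <- stats::rpois(1, model$ocular_artifact_rate / 60 * n / fs)
  oc <- numeric(n)
  heog <- stats::rnorm(n, sd = 2)
  if (n_ev > 0) {
    starts <- sort(sample.int(max(1, n - length(pulse)), n_ev, replace = TRUE))
    for (s in starts) {
      amp <- model$ocular_amp * stats::runif(1, 0.6, 1.3) *
        sample(c(1, -1), 1, prob = c(0.8, 0.2))
      j <- s:(s + length(pulse) - 1)
      oc[j] <- oc[j] + amp * pulse
      heog[j] <- heog[j] + amp * pulse * sample(c(1, -1), 1)
    }
  }

  sig <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    W_own <- stats::fft(stats::rnorm(n))
    own <- shape_noise(W_own, fs, b_non)
    bg <- sqrt(1 - mix^2) * own + mix * shared
    if (two_regimes) {
      own_mw <- shape_noise(W_own, fs, b_mw)
      bg_mw <- sqrt(1 - mix^2) * own_mw + mix * shared_mw
      bg <- (1 - w_mw) * bg + w_mw * bg_mw
    }
    sig[ch, ] <- model$noise_sd * bg + w_alpha[ch] * alpha_sig +
      osc + w_oc[ch] * oc
  }
  list(signal = sig, heog = heog)
}

#' Generate a synthetic cohort
#'
#' One [generate_session()] per participant, with independent per-participant
#' random streams derived reproducibly from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param model a [signal_model()].
#' @return list of `mw_session` objects named by participant id.
#' @export
generate_cohort <- function(spec, model) {
  ids <- sprintf("S%02d", seq_len(spec$n_participants))
  stats::setNames(lapply(ids, function(id) generate_session(spec, model, id)),
                  ids)
}

#' @export
print.mw_session <- function(x, ...) {
  cat(sprintf("<mw_session %s> %d ch x %d samples @ %g Hz (%.1f min), %d probes",
              x$participant_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, ncol(x$signal) / x$sampling_rate / 60,
              if (is.null(x$probes)) 0L else nrow(x$probes)))
  if (!is.null(x$rejected_intervals) && nrow(x$rejected_intervals) > 0)
    cat(sprintf(", %d rejected intervals", nrow(x$rejected_intervals)))
  cat("\n")
  invisible(x)
}
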