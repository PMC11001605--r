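# Continuous-signal conditioning: band-pass filter, common average reference,
# anti-aliased downsampling, and robust sliding-RMS rejection of abrupt
# high-amplitude segments. The fixed pipeline order is
# bandpass -> common average -> downsample -> rejection.

#' Band-pass filter a session
#'
#' Zero-phase FIR band-pass (Hamming window design). The filter order is
#' chosen automatically from a transition width of 25% of each cutoff, and
#' the symmetric kernel is applied with exact group-delay compensation, so
#' the output is zero-phase.
#'
#' @param session an `mw_session`.
#' @param low,high band edges in Hz (defaults 1 and 40).
#' @return the session with filtered `signal` (and `heog`, if present).
#' @export
bandpass <- function(session, low = 1, high = 40) {
  fs <- session$sampling_rate
  if (!(low < high)) stop("low must be < high")
  if (high >= fs / 2) stop("high cutoff must be below the Nyquist frequency")
  n <- ncol(session$signal)
  ord <- fir_order(min(0.25 * low, 0.25 * high), fs, n)
  h <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  session$signal <- fir_filter_rows(session$signal, h)
  if (!is.null(session$heog))
    session$heog <- drop(fir_filter_rows(matrix(session$heog, 1), h))
  session$preproc$filter <- list(low = low, high = high, order = ord)
  session
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is zero.
#'
#' @param session an `mw_session` with at least 2 channels.
#' @return the re-referenced session.
#' @export
rereference_common_average <- function(session) {
  if (nrow(session$signal) < 2)
    stop("common average reference requires at least 2 channels")
  avg <- colMeans(session$signal)
  session$signal <- sweep(session$signal, 2, avg)
  session$preproc$reference <- "common_average"
  session
}

#' Downsample a session
#'
#' Anti-aliased decimation to `target` Hz. The original rate must be an
#' integer multiple of the target; an FIR low-pass at 80% of the target
#' Nyquist is applied before taking every q-th sample. Probe times are kept
#' in seconds and are unchanged.
#'
#' @param session an `mw_session`.
#' @param target target sampling rate in Hz (default 256).
#' @return the downsampled session.
#' @export
downsample <- function(session, target = 256) {
  fs <- session$sampling_rate
  if (target > fs) stop("target rate exceeds original rate")
  q <- fs / target
  if (abs(q - round(q)) > 1e-9)
    stop("original rate must be an integer multiple of the target")
  q <- round(q)
  if (q > 1) {
    cutoff <- 0.8 * target / 2
    ord <- fir_order(0.2 * target / 2, fs, ncol(session$signal))
    h <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
    session$signal <- fir_filter_rows(session$signal, h)
    keep <- seq(1, by = q, length.out = floor(ncol(session$signal) / q))
    session$signal <- session$signal[, keep, drop = FALSE]
    if (!is.null(session$heog)) {
      hh <- drop(fir_filter_rows(matrix(session$heog, 1), h))
      session$heog <- hh[keep]
    }
  }
  session$sampling_rate <- target
  session$preproc$resample <- list(target_hz = target, factor = q)
  session
}

#' Mark abrupt high-amplitude segments for rejection
#'
#' Stand-in for calibration-based artifact removal that, like the analysis it
#' supports, only deletes bad stretches: a sliding-window RMS is computed per
#' channel, robust z-scores are taken against the median/MAD of all window
#' RMS values, and any window exceeding `z_threshold` in any channel is added
#' to `rejected_intervals`. The signal itself is untouched; downstream
#' windowing drops epochs that overlap a rejected interval.
#'
#' @param session an `mw_session` of at least 30 s.
#' @param z_threshold robust z cutoff (default 8).
#' @param window_s sliding window length in seconds (default 1); step is half
#'   a window.
#' @return the session with `rejected_intervals` (matrix of `[start_s, end_s)`
#'   rows, merged and sorted).
#' @export
reject_abrupt_segments <- function(session, z_threshold = 8, window_s = 1) {
  fs <- session$sampling_rate
  n <- ncol(session$signal)
  if (n / fs < 30)
    stop("need at least 30 s of data to calibrate the rejection threshold")
  win <- round(window_s * fs)
  step <- max(1, round(win / 2))
  starts <- seq(1, n - win + 1, by = step)
  nch <- nrow(session$signal)
  rms <- matrix(0, nch, length(starts))
  x2 <- session$signal^2
  cs <- cbind(0, t(apply(x2, 1, cumsum)))  # nch x (n+1)
  for (j in seq_along(starts)) {
    s <- starts[j]
    rms[, j] <- sqrt((cs[, s + win] - cs[, s]) / win)
  }
  bad <- logical(length(starts))
  for (ch in seq_len(nch)) {
    med <- stats::median(rms[ch, ])
    mad <- stats::mad(rms[ch, ])
    if (mad == 0) mad <- .Machine$double.eps
    bad <- bad | (rms[ch, ] - med) / mad > z_threshold
  }
  if (all(bad)) stop("all data rejected; lower z_threshold or check input")
  iv <- cbind((starts[bad] - 1) / fs, (starts[bad] - 1) / fs + window_s)
  session$rejected_intervals <- merge_intervals(iv)
  session$preproc$rejection <- list(
    method = "robust_z_sliding_rms",
    note = "threshold-deletion stand-in for calibration-based artifact removal",
    z_threshold = z_threshold, window_s = window_s, n_windows_flagged = sum(bad))
  session
}

#' Regress a horizontal EOG reference out of every channel
#'
#' Optional ocular-activity removal: the least-squares projection of each
#' channel onto the (centered) HEOG series is subtracted, leaving residuals
#' orthogonal to the reference.
#'
#' @param session an `mw_session`.
#' @param heog reference series, same length as the signal; defaults to the
#'   session's own `heog` trace when present.
#' @return the session with the HEOG component removed.
#' @export
regress_out_heog <- function(session, heog = session$heog) {
  if (is.null(heog)) stop("no HEOG reference available")
  if (length(heog) != ncol(session$signal))
    stop("heog length must match the signal")
  h <- heog - mean(heog)
  denom <- sum(h^2)
  if (denom > 0) {
    beta <- as.vector(session$signal %*% h) / denom
    session$signal <- session$signal - outer(beta, h)
  }
  session$preproc$ocular <- list(method = "heog_regression")
  session
}

#' Default preprocessing configuration
#'
#' @param low,high band-pass edges in Hz.
#' @param target_hz downsampling target.
#' @param z_threshold,window_s segment-rejection settings.
#' @param ocular `"none"` or `"heog_regression"`.
#' @export
preproc_config <- function(low = 1, high = 40, target_hz = 256,
                           z_threshold = 8, window_s = 1,
                           ocular = c("none", "heog_regression")) {
  list(filter = list(low = low, high = high),
       resample = list(target_hz = target_hz),
       asr = list(z_threshold = z_threshold, window_s = window_s),
       ocular = list(method = match.arg(ocular)))
}

#' Run the full preprocessing pipeline on a session
#'
#' Fixed order: band-pass, common average reference, downsample, abrupt
#' segment rejection (and optionally HEOG regression before re-referencing).
#'
#' @param session an `mw_session`.
#' @param config a [preproc_config()].
#' @return the cleaned session (with `rejected_intervals` populated).
#' @export
preprocess_session <- function(session, config = preproc_config()) {
  session <- bandpass(session, config$filter$low, config$filter$high)
  if (identical(config$ocular$method, "heog_regression"))
    session <- regress_out_heog(session)
  session <- rereference_common_average(session)
  session <- downsample(session, config$resample$target_hz)
  reject_abrupt_segments(session, config$asr$z_threshold, config$asr$window_s)
}
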