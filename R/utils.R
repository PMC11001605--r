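#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed
#'
#' Mixes the master seed with any number of extra keys (integers or strings)
#' into a 31-bit integer, so that per-participant / per-fold random streams
#' are decoupled but fully determined by the master seed.
#'
#' @param seed master seed (integer).
#' @param ... additional keys (character or numeric scalars).
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (key in list(...)) {
    vals <- if (is.character(key)) utf8ToInt(key) else as.numeric(key)
    for (v in vals) h <- (h * 31 + (v %% mod) + 7) %% mod
  }
  as.integer(h)
}

# Run code with a local RNG stream; the caller's RNG state is restored on exit.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- FIR filtering -----------------------------------------------------------

# Even filter order from a Hamming-window design rule: order ~ 3.3 / (tw / fs),
# where tw is the transition width in Hz. Capped so short signals stay usable.
fir_order <- function(transition_hz, fs, n_samples) {
  ord <- ceiling(3.3 * fs / transition_hz)
  cap <- max(4, 2 * floor((n_samples - 1) / 6))
  if (ord > cap) ord <- cap
  ord + (ord %% 2)  # even order -> odd-length symmetric kernel
}

# Zero-phase FIR filtering of each row of `x` (channels x samples) by FFT
# convolution. `h` must be an odd-length symmetric (linear-phase) kernel; the
# group delay is compensated exactly. Edges are mirror-padded. FFT lengths
# are padded to highly composite sizes so mixed-radix FFTs stay fast.
fir_filter_rows <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  gd <- (length(h) - 1) / 2
  n <- ncol(x)
  pad <- min(gd, n - 1)
  np <- n + 2 * pad
  L <- stats::nextn(np + length(h) - 1, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(L - length(h))))
  out <- x
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    vp <- c(rev(v[seq_len(pad) + 1]), v, rev(v[n - seq_len(pad)]))
    full <- Re(stats::fft(stats::fft(c(vp, numeric(L - np))) * H,
                          inverse = TRUE)) / L
    out[ch, ] <- full[(gd + pad + 1):(gd + pad + n)]
  }
  out
}

# --- intervals ---------------------------------------------------------------

# Merge overlapping/adjacent [start, end) intervals given as a 2-column matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

# TRUE if [a, b) overlaps any row of `iv` ([start, end) intervals).
overlaps_any <- function(a, b, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(FALSE)
  any(a < iv[, 2] & iv[, 1] < b)
}

# --- spectra -----------------------------------------------------------------

#' Welch power spectral density
#'
#' Segment-averaged periodogram with a Hann taper and 50% overlap; used to
#' verify the spectral slope of generated background activity.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 4).
#' @return data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_s = 4) {
  nseg <- round(seg_s * fs)
  if (nseg > length(x)) nseg <- length(x)
  step <- max(1, floor(nseg / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / (fs * sum(w^2))
    acc <- acc + p[seq_along(acc)]
  }
  psd <- acc / length(starts)
  data.frame(freq = (seq_along(psd) - 1) * fs / nseg, psd = psd)
}

# Log-log slope of a Welch PSD between two frequencies.
psd_slope <- function(psd_df, f_lo, f_hi) {
  sel <- psd_df$freq >= f_lo & psd_df$freq <= f_hi & psd_df$psd > 0
  stats::coef(stats::lm(log(psd) ~ log(freq), data = psd_df[sel, ]))[[2]]
}
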