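# Band power via a 5-level Daubechies-4 discrete wavelet transform
# (orthonormal Mallat pyramid with periodic boundary handling), computed as
# the mean squared amplitude of each reconstructed band signal. At 256 Hz the
# dyadic bands approximate the canonical EEG bands:
#   A5 0-4 Hz -> delta, D5 4-8 Hz -> theta, D4 8-16 Hz -> alpha,
#   D3 16-32 Hz -> beta.
# The printed band edges (8-12, 12-30 Hz) cannot align exactly with dyadic
# splits; this mapping is recorded in the feature descriptors.

db4_filters <- function() {
  h <- c(0.230377813308855230, 0.714846570552541500,
         0.630880767929590400, -0.027983769416983850,
         -0.187034811718881140, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
  g <- c(1, -1) * rev(h)  # g_i = (-1)^(i-1) h_(L+1-i), recycled sign pattern
  list(h = h, g = g)
}

# One periodic analysis step: y[k] = sum_i f[i] x[(2k + i) mod n].
dwt_step <- function(x, f) {
  n <- length(x)
  out <- numeric(n / 2)
  for (i in seq_along(f)) {
    idx <- ((2 * (seq_len(n / 2) - 1) + (i - 1)) %% n) + 1
    out <- out + f[i] * x[idx]
  }
  out
}

# Adjoint (= inverse, by orthogonality) of one analysis step.
idwt_step <- function(a, d, filt) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (i in seq_along(filt$h)) {
    idx <- ((2 * (seq_len(n / 2) - 1) + (i - 1)) %% n) + 1
    x[idx] <- x[idx] + filt$h[i] * a + filt$g[i] * d
  }
  x
}

#' Discrete wavelet decomposition (Daubechies-4, periodic)
#'
#' @param x numeric series; its length must be divisible by `2^levels`.
#' @param levels number of decomposition levels (default 5).
#' @return list with `details` (list D1..Dlevels, finest first) and `approx`
#'   (the final approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 5) {
  if (length(x) %% 2^levels != 0)
    stop("series length must be divisible by 2^levels")
  filt <- db4_filters()
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    details[[j]] <- dwt_step(a, filt$g)
    a <- dwt_step(a, filt$h)
  }
  names(details) <- paste0("D", seq_len(levels))
  list(details = details, approx = a)
}

#' Inverse Daubechies-4 wavelet transform
#'
#' @param decomp a decomposition from [dwt_db4()] (coefficient sets may be
#'   zeroed to reconstruct a single band).
#' @return the reconstructed series.
#' @export
idwt_db4 <- function(decomp) {
  filt <- db4_filters()
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]], filt)
  a
}

#' Wavelet band power of an epoch channel
#'
#' 5-level Daubechies-4 decomposition at 256 Hz; each band signal is
#' reconstructed from its coefficient set alone and its mean squared
#' amplitude (microvolts squared) returned.
#'
#' @param x numeric series sampled at 256 Hz; length divisible by 32 (a 10 s
#'   epoch of 2560 samples qualifies).
#' @param fs sampling rate; must be 256 for the dyadic band mapping to hold.
#' @return named vector `c(delta, theta, alpha, beta)` in microvolts squared.
#' @export
band_power <- function(x, fs = 256) {
  if (fs != 256)
    stop("band mapping is defined for 256 Hz; downsample first")
  if (length(x) < 32) stop("series too short for a 5-level decomposition")
  n <- 32 * floor(length(x) / 32)
  if (n < length(x)) x <- x[seq_len(n)]
  dec <- dwt_db4(x, levels = 5)
  band_sets <- list(delta = "A", theta = "D5", alpha = "D4", beta = "D3")
  out <- vapply(band_sets, function(keep) {
    d <- dec
    if (keep != "A") d$approx[] <- 0
    for (nm in names(d$details)) if (nm != keep) d$details[[nm]][] <- 0
    mean(idwt_db4(d)^2)
  }, numeric(1))
  names(out) <- names(band_sets)
  out
}
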