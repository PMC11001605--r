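# Regularity metrics: sample entropy, permutation entropy, dispersion
# entropy, and their coarse-grained multiscale variants.

#' Coarse-grain a series
#'
#' Scale-s series obtained by averaging s consecutive samples in
#' non-overlapping blocks; the basis of every multiscale metric. Scale 1 is
#' the identity.
#'
#' @param x numeric series.
#' @param s integer scale >= 1.
#' @return series of length `floor(length(x) / s)`.
#' @export
coarse_grain <- function(x, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1) stop("scale must be a positive integer")
  if (length(x) < s) stop("series shorter than scale")
  if (s == 1) return(x)
  n <- floor(length(x) / s)
  colMeans(matrix(x[seq_len(n * s)], nrow = s))
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where B and A count pairs of templates of length `m` and
#' `m + 1` that match under the Chebyshev distance within tolerance
#' `r = r_frac * sd(x)`, self-matches excluded. Lower values indicate a more
#' regular series. Returns `NA` (with a warning) when no templates match at
#' either length, which the feature matrix records as missing.
#'
#' @param x numeric series (length >= 10 m recommended).
#' @param m embedding dimension (default 2).
#' @param r_frac tolerance as a fraction of the series SD (default 0.2).
#' @param r absolute tolerance override; when given, `r_frac` is ignored.
#' @return entropy in nats, or `NA_real_` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2, r = NULL) {
  n <- length(x)
  if (n < m + 2) stop("series too short for the requested embedding")
  if (is.null(r)) r <- r_frac * stats::sd(x)
  if (r < 0) stop("tolerance must be non-negative")
  D <- abs(outer(x, x, "-")) <= r
  nt <- n - m  # templates 1..nt support both length-m and length-(m+1) counts
  M <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) {
    for (k in seq_len(m - 1))
      M <- M & D[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE]
  }
  B <- (sum(M) - nt) / 2  # remove self-matches on the diagonal
  A <- (sum(M & D[seq_len(nt) + m, seq_len(nt) + m, drop = FALSE]) - nt) / 2
  if (A <= 0 || B <= 0) {
    warning("sample entropy undefined (no matching templates)", call. = FALSE)
    return(NA_real_)
  }
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns (rank orderings)
#' of length-`m` motifs taken at delay `tau`. Ties are broken by temporal
#' order. Reported in bits; when `normalized`, divided by `log2(m!)` so the
#' value lies in `[0, 1]`.
#'
#' @param x numeric series.
#' @param m pattern order, 2..7 (default 3).
#' @param tau embedding delay in samples (default 1).
#' @param normalized divide by `log2(m!)` (default TRUE).
#' @return entropy in bits (or normalized units).
#' @export
permutation_entropy <- function(x, m = 3, tau = 1, normalized = TRUE) {
  if (m > 7) stop("pattern order above 7 is not supported (m! blow-up)")
  if (m < 2) stop("pattern order must be at least 2")
  n <- length(x)
  nm <- n - (m - 1) * tau
  if (nm < 2) stop("series too short for the requested order and delay")
  E <- vapply(0:(m - 1), function(k) x[seq_len(nm) + k * tau], numeric(nm))
  if (nm == 1) E <- matrix(E, nrow = 1)
  # Lehmer code of each motif: c_k = #{j < k : x_j > x_k} (ties -> earlier wins)
  id <- integer(nm)
  for (k in 2:m) {
    ck <- integer(nm)
    for (j in seq_len(k - 1)) ck <- ck + (E[, j] > E[, k])
    id <- id * k + ck
  }
  p <- tabulate(id + 1L, nbins = factorial(m))
  p <- p[p > 0] / nm
  h <- -sum(p * log2(p))
  if (normalized) h / log2(factorial(m)) else h
}

#' Dispersion entropy
#'
#' Amplitudes are mapped to `c` classes (by default through the normal
#' cumulative distribution function, then rounding), and the Shannon entropy
#' of the distribution of length-`m` dispersion patterns is returned in nats
#' (optionally normalized by `ln(c^m)`). A zero-variance series maps to a
#' single class and returns 0.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param c number of classes (default 6).
#' @param map `"NCDF"` (normal CDF) or `"linear"` (min-max).
#' @param normalized divide by `ln(c^m)` (default FALSE).
#' @return entropy in nats (or normalized units).
#' @export
dispersion_entropy <- function(x, m = 2, c = 6, map = c("NCDF", "linear"),
                               normalized = FALSE) {
  map <- match.arg(map)
  if (c < 2) stop("need at least 2 classes")
  n <- length(x)
  if (n < m + 1) stop("series too short for the requested embedding")
  if (map == "NCDF") {
    s <- stats::sd(x)
    y <- if (s == 0) rep(0.5, n) else stats::pnorm(x, mean(x), s)
  } else {
    rng <- range(x)
    y <- if (rng[1] == rng[2]) rep(0.5, n) else (x - rng[1]) / (rng[2] - rng[1])
  }
  z <- pmin(pmax(round(c * y + 0.5), 1L), c)
  nm <- n - m + 1
  id <- integer(nm)
  for (k in 0:(m - 1)) id <- id * c + (z[seq_len(nm) + k] - 1L)
  p <- tabulate(id + 1L, nbins = c^m)
  p <- p[p > 0] / nm
  h <- -sum(p * log(p))
  if (normalized) h / log(c^m) else h
}

#' Multiscale entropy curve
#'
#' Applies a mono-scale regularity metric to coarse-grained versions of the
#' series at each requested scale. Scales whose coarse-grained series is too
#' short for a stable estimate yield `NA`. For sample entropy the matching
#' tolerance is fixed at `se_r` times the SD of the *original* series
#' (classic multiscale-entropy convention), so averaging-induced variance
#' loss is reflected in the curve.
#'
#' @param x numeric series.
#' @param metric `"SE"`, `"PE"` or `"DE"`.
#' @param params a [complexity_params()].
#' @return named numeric vector, one value per scale in `params$scales`.
#' @export
multiscale <- function(x, metric = c("SE", "PE", "DE"),
                       params = complexity_params()) {
  metric <- match.arg(metric)
  min_len <- switch(metric,
                    SE = 10 * params$se_m,
                    PE = params$pe_m * params$pe_tau + 10,
                    DE = 10 * params$de_m)
  r_abs <- params$se_r * stats::sd(x)
  out <- vapply(params$scales, function(s) {
    xs_len <- floor(length(x) / s)
    if (xs_len < min_len) return(NA_real_)
    xs <- coarse_grain(x, s)
    switch(metric,
           SE = suppressWarnings(sample_entropy(xs, params$se_m, r = r_abs)),
           PE = permutation_entropy(xs, params$pe_m, params$pe_tau,
                                    normalized = TRUE),
           DE = dispersion_entropy(xs, params$de_m, params$de_c, params$de_map))
  }, numeric(1))
  stats::setNames(out, paste0("s", params$scales))
}
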