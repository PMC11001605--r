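# Temporal-dimensionality metrics: Higuchi and Katz fractal dimensions and
# detrended fluctuation analysis. All treat the series as a geometric object
# and make no stationarity assumption.

#' Higuchi fractal dimension
#'
#' Mean normalized curve length L(k) is computed for lags k = 1..`k_max`
#' over all k phase offsets; the fractal dimension is the least-squares slope
#' of log L(k) against log(1/k). Values lie in `[1, 2]` for curves: ~1 for
#' smooth lines, ~2 for uncorrelated noise. A constant series returns 1 by
#' convention.
#'
#' @param x numeric series (length >= 10 `k_max` recommended).
#' @param k_max maximum lag (default 10).
#' @return estimated fractal dimension.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  n <- length(x)
  if (n < k_max + 2) stop("series too short for the requested k_max")
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    d <- abs(x[(k + 1):n] - x[seq_len(n - k)])  # |x[i+k] - x[i]|
    Lm <- numeric(k)
    for (m0 in seq_len(k)) {
      steps <- floor((n - m0) / k)
      if (steps < 1) { Lm[m0] <- NA; next }
      idx <- m0 + (seq_len(steps) - 1) * k  # start indices of the k-lag steps
      Lm[m0] <- sum(d[idx]) * (n - 1) / (steps * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  if (all(Lk == 0)) return(1.0)  # constant series
  fit <- stats::lm(log(Lk) ~ log(1 / seq_len(k_max)))
  unname(stats::coef(fit)[2])
}

#' Katz fractal dimension
#'
#' `FD = log10(n) / (log10(n) + log10(d / L))` where `L` is the total path
#' length through the points `(i, x_i)`, `d` the maximum distance from the
#' first point, and `n` the number of steps. Exactly 1 for straight lines
#' (where `d = L`); constant series return 1 by convention.
#'
#' @param x numeric series of length >= 3.
#' @return estimated fractal dimension.
#' @export
katz_fd <- function(x) {
  if (length(x) < 3) stop("need at least 3 points")
  n <- length(x) - 1
  dx <- diff(x)
  L <- sum(sqrt(1 + dx^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (L == 0 || d == 0) return(1.0)
  log10(n) / (log10(n) + log10(d / L))
}

#' Detrended fluctuation analysis
#'
#' The mean-removed series is integrated into a profile; for each box size
#' the profile is split into non-overlapping boxes, an order-`order`
#' polynomial is fitted per box, and F(n) is the RMS residual. The scaling
#' exponent alpha is the log-log slope of F(n) against n: 0.5 for
#' uncorrelated noise, 1.5 for a Brownian path.
#'
#' @param x numeric series.
#' @param box_sizes integer box sizes; default 10 log-spaced sizes from 16 to
#'   `length(x) / 4`.
#' @param order detrending polynomial order (default 1).
#' @return list with `alpha` (the exponent), `box_sizes` and `fluctuation`
#'   (F(n) per box size).
#' @export
dfa <- function(x, box_sizes = NULL, order = 1) {
  n <- length(x)
  if (is.null(box_sizes)) {
    hi <- floor(n / 4)
    if (hi < 16) stop("series too short for default box sizes")
    box_sizes <- unique(round(exp(seq(log(16), log(hi), length.out = 10))))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= order + 2 & box_sizes <= floor(n / 2)]
  if (length(box_sizes) < 3) stop("need at least 3 usable box sizes")
  if (n < 4 * max(box_sizes))
    warning("series shorter than 4x the largest box size; estimate may be unstable",
            call. = FALSE)
  y <- cumsum(x - mean(x))
  Fn <- vapply(box_sizes, function(s) {
    nbox <- floor(n / s)
    t <- seq_len(s)
    X <- stats::poly(t, degree = order, raw = TRUE)
    res2 <- 0
    for (b in seq_len(nbox)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      fit <- stats::lm.fit(cbind(1, X), seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (nbox * s))
  }, numeric(1))
  ok <- Fn > 0
  if (sum(ok) < 3) {
    # degenerate (e.g. perfectly detrendable) profile: no scaling to estimate
    return(list(alpha = NA_real_, box_sizes = box_sizes, fluctuation = Fn))
  }
  fit <- stats::lm(log(Fn[ok]) ~ log(box_sizes[ok]))
  list(alpha = unname(stats::coef(fit)[2]),
       box_sizes = box_sizes, fluctuation = Fn)
}
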