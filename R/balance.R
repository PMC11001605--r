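#' SMOTE class balancing
#'
#' Equalizes the two class counts of a training set by adding synthetic
#' minority-class samples: each synthetic point is a convex combination of a
#' minority sample and one of its `k` nearest minority neighbors (Euclidean).
#' Original samples are preserved verbatim and come first in the output. Only
#' ever applied to training folds.
#'
#' @param x numeric matrix (samples x features), no missing values.
#' @param y class labels (two levels).
#' @param k neighbor count (default 5; reduced with a warning when the
#'   minority class has fewer than `k + 1` samples).
#' @param seed RNG seed for neighbor and interpolation draws.
#' @return list with `x`, `y` (balanced), and `n_synthetic`.
#' @export
smote_balance <- function(x, y, k = 5, seed = 1L) {
  stopifnot(nrow(x) == length(y), !anyNA(x))
  tab <- table(y)
  if (length(tab) != 2) stop("smote_balance expects exactly two classes")
  if (tab[1] == tab[2])
    return(list(x = x, y = y, n_synthetic = 0L))
  minority <- names(tab)[which.min(tab)]
  idx_min <- which(y == minority)
  n_needed <- abs(diff(tab))[[1]]
  if (length(idx_min) < 2)
    stop("minority class needs at least 2 samples for interpolation")
  if (length(idx_min) <= k) {
    k <- length(idx_min) - 1L
    warning(sprintf("SMOTE k reduced to %d (minority size)", k), call. = FALSE)
  }
  xm <- x[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  synth <- with_local_seed(seed, {
    base_i <- sample(nrow(xm), n_needed, replace = TRUE)
    nb_i <- vapply(base_i, function(i) as.integer(nn[i, sample.int(k, 1)]),
                   integer(1))
    gap <- stats::runif(n_needed)
    xm[base_i, , drop = FALSE] +
      gap * (xm[nb_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
  })
  list(x = rbind(x, synth),
       y = c(y, rep(minority, n_needed)),
       n_synthetic = as.integer(n_needed))
}
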