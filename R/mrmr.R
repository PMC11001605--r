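# Minimum-redundancy maximum-relevance feature selection (MID criterion)
# with mutual information estimated on equal-frequency discretized features.

# Equal-frequency discretization into at most `bins` levels.
discretize_ef <- function(x, bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))  # constant feature
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# Plug-in mutual information (nats) between two discrete vectors.
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

#' MRMR feature selection
#'
#' Greedy minimum-redundancy maximum-relevance ordering: the first feature
#' maximizes mutual information with the label; each subsequent feature
#' maximizes relevance minus the mean mutual information with the already
#' selected set (the MID, "difference", criterion). Features are discretized
#' into equal-frequency bins before MI estimation.
#'
#' @param x numeric matrix (samples x features), finite values.
#' @param y class labels.
#' @param K number of features to select (`<= ncol(x)`).
#' @param bins discretization bins (default 8).
#' @return integer vector of selected column indices, in selection order.
#' @export
mrmr_select <- function(x, y, K, bins = 8) {
  p <- ncol(x)
  if (K > p) stop("K exceeds the number of features")
  if (!all(is.finite(x))) stop("features must be finite (impute first)")
  disc <- lapply(seq_len(p), function(j) discretize_ef(x[, j], bins))
  yf <- as.integer(factor(y))
  relevance <- vapply(disc, mi_discrete, numeric(1), b = yf)
  selected <- integer(0)
  redundancy <- matrix(NA_real_, nrow = K, ncol = p)  # MI(candidate, selected_i)
  for (step in seq_len(K)) {
    if (step == 1) {
      score <- relevance
    } else {
      red_mean <- colMeans(redundancy[seq_len(step - 1), , drop = FALSE])
      score <- relevance - red_mean
    }
    score[selected] <- -Inf
    pick <- which.max(score)
    selected <- c(selected, pick)
    if (step < K) {
      redundancy[step, ] <- vapply(disc, mi_discrete, numeric(1),
                                   b = disc[[pick]])
    }
  }
  selected
}
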