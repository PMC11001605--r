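# Independent brute-force oracles used to validate the package's metric
# implementations. These are deliberately naive O(N^2) / exhaustive
# re-derivations and share no code with the package.

# Sample entropy by explicit template enumeration (Chebyshev matching,
# self-matches excluded).
oracle_sample_entropy <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in 1:(n - m)) for (j in 1:(n - m)) {
    if (i == j) next
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Permutation entropy by exhaustive ordinal-pattern counting (ties broken by
# temporal order), in bits.
oracle_permutation_entropy <- function(x, m, tau = 1, normalized = TRUE) {
  n <- length(x)
  nm <- n - (m - 1) * tau
  pats <- character(nm)
  for (i in seq_len(nm)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = "-")  # order() breaks ties by index
  }
  p <- table(pats) / nm
  h <- -sum(p * log2(p))
  if (normalized) h / log2(factorial(m)) else h
}

# Dispersion entropy by explicit symbolization and pattern counting, nats.
oracle_dispersion_entropy <- function(x, m, cc, map = "NCDF") {
  n <- length(x)
  y <- if (map == "NCDF") {
    if (sd(x) == 0) rep(0.5, n) else pnorm(x, mean(x), sd(x))
  } else {
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, n) else (x - r[1]) / (r[2] - r[1])
  }
  z <- pmin(pmax(round(cc * y + 0.5), 1), cc)
  pats <- character(n - m + 1)
  for (i in seq_len(n - m + 1)) pats[i] <- paste(z[i:(i + m - 1)], collapse = ",")
  p <- table(pats) / length(pats)
  -sum(p * log(p))
}

# Higuchi curve lengths by direct summation over every lag and phase.
oracle_higuchi_fd <- function(x, k_max) {
  n <- length(x)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- c()
    for (m0 in 1:k) {
      imax <- floor((n - m0) / k)
      if (imax < 1) next
      s <- 0
      for (i in 1:imax) s <- s + abs(x[m0 + i * k] - x[m0 + (i - 1) * k])
      Lm <- c(Lm, s * (n - 1) / (imax * k) / k)
    }
    Lk[k] <- mean(Lm)
  }
  fit <- lm(log(Lk) ~ log(1 / (1:k_max)))
  unname(coef(fit)[2])
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  pos <- labels == "MW"
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Minimal session constructor for preprocessing / windowing tests.
make_session <- function(signal, fs, labels = paste0("ch", seq_len(nrow(signal))),
                         probes = NULL, id = "T01", heog = NULL) {
  structure(list(signal = signal, sampling_rate = fs, channel_labels = labels,
                 probes = probes,
                 blocks = data.frame(block = 1L, start_s = 0,
                                     end_s = ncol(signal) / fs),
                 heog = heog, participant_id = id,
                 rejected_intervals = NULL, preproc = list()),
            class = "mw_session")
}

# Probe table row helper.
make_probe <- function(time_s, probe_id = "p1", response = 3L, confidence = 3L) {
  data.frame(probe_id = probe_id, time_s = time_s, block = 1L,
             trigger = "random", response = response, confidence = confidence,
             drowsiness = 4L, latent_mw = response == 3L,
             stringsAsFactors = FALSE)
}

# Scaled-down cohort conditions used in simulation-based tests: fewer,
# shorter blocks and fewer channels than a full recording session, so the
# suite exercises the complete pipeline at laptop scale.
small_cohort_spec <- function(n_participants, seed, fs = 256,
                              n_blocks = 4, block_duration = 600) {
  cohort_spec(n_participants = n_participants, n_blocks = n_blocks,
              block_duration = block_duration, sampling_rate = fs,
              n_channels = 8,
              channel_labels = c("FP1", "FP2", "F3", "F4",
                                 "C3", "C4", "O1", "O2"),
              seed = seed)
}
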