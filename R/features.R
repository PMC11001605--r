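# Assembly of described feature matrices from labeled epochs: one row per
# epoch, one column per (family, channel, scale-or-band) descriptor.

#' Parameters of the complexity feature families
#'
#' Defaults follow the metrics' original publications (sample entropy m = 2,
#' r = 0.2 SD; permutation entropy m = 3, tau = 1; dispersion entropy c = 6,
#' m = 2, normal-CDF mapping) and the multiscale range 1..14 with the
#' analysis subset 1..10.
#'
#' @param se_m,se_r sample entropy embedding dimension and tolerance
#'   fraction.
#' @param pe_m,pe_tau permutation entropy order and delay.
#' @param de_m,de_c,de_map dispersion entropy embedding, class count and
#'   amplitude mapping.
#' @param scales integer coarse-graining scales (default 1:14).
#' @param hfd_kmax Higuchi maximum lag.
#' @param dfa_order DFA detrending order.
#' @param bands band edges in Hz (delta/theta/alpha/beta); informational --
#'   the wavelet mapping is dyadic, see [band_power()].
#' @return object of class `mw_complexity_params`.
#' @export
complexity_params <- function(se_m = 2, se_r = 0.2,
                              pe_m = 3, pe_tau = 1,
                              de_m = 2, de_c = 6, de_map = "NCDF",
                              scales = 1:14,
                              hfd_kmax = 10,
                              dfa_order = 1,
                              bands = list(delta = c(1, 4), theta = c(4, 8),
                                           alpha = c(8, 12), beta = c(12, 30))) {
  stopifnot(all(scales >= 1), all(scales == round(scales)),
            de_c >= 2, hfd_kmax >= 2, dfa_order >= 0)
  structure(list(se_m = se_m, se_r = se_r, pe_m = pe_m, pe_tau = pe_tau,
                 de_m = de_m, de_c = de_c, de_map = de_map,
                 scales = as.integer(scales), hfd_kmax = hfd_kmax,
                 dfa_order = dfa_order, bands = bands),
            class = "mw_complexity_params")
}

FEATURE_FAMILIES <- c("MSE", "MPE", "MDE", "HFD", "KFD", "DFA", "BP")

# Descriptor table for one family over the given channels.
family_descriptors <- function(family, channels, params) {
  if (family %in% c("MSE", "MPE", "MDE")) {
    expand.grid(scale_or_band = paste0("s", params$scales),
                channel = channels, family = family,
                stringsAsFactors = FALSE)[, c("family", "channel", "scale_or_band")]
  } else if (family == "BP") {
    expand.grid(scale_or_band = names(params$bands),
                channel = channels, family = family,
                stringsAsFactors = FALSE)[, c("family", "channel", "scale_or_band")]
  } else {
    data.frame(family = family, channel = channels, scale_or_band = "",
               stringsAsFactors = FALSE)
  }
}

# All features of one family for one epoch (channels x samples matrix),
# in descriptor order (channel-major, scale/band-minor).
epoch_family_features <- function(epoch, family, params, fs) {
  nch <- nrow(epoch)
  if (family %in% c("MSE", "MPE", "MDE")) {
    metric <- c(MSE = "SE", MPE = "PE", MDE = "DE")[[family]]
    as.vector(vapply(seq_len(nch), function(ch)
      multiscale(epoch[ch, ], metric, params),
      numeric(length(params$scales))))
  } else if (family == "BP") {
    as.vector(vapply(seq_len(nch), function(ch)
      band_power(epoch[ch, ], fs = fs), numeric(4)))
  } else {
    vapply(seq_len(nch), function(ch) {
      x <- epoch[ch, ]
      switch(family,
             HFD = higuchi_fd(x, params$hfd_kmax),
             KFD = katz_fd(x),
             DFA = dfa(x, order = params$dfa_order)$alpha)
    }, numeric(1))
  }
}

#' Extract the feature matrix of an epoch set
#'
#' Computes every requested feature family for every epoch and channel.
#' Multiscale families contribute `length(scales) * n_channels` columns each,
#' band power `4 * n_channels`, and HFD/KFD/DFA `n_channels` each. Epochs
#' with more than 20% missing features are dropped with a warning; remaining
#' missing values stay `NA` (imputation happens inside training folds).
#'
#' @param epoch_set an `mw_epoch_set` from [build_epoch_set()].
#' @param params a [complexity_params()].
#' @param families subset of `c("MSE","MPE","MDE","HFD","KFD","DFA","BP")`.
#' @return object of class `mw_features`: list with `values` (epochs x
#'   features matrix), `descriptors` (data.frame: family, channel,
#'   scale_or_band), `meta` (epoch metadata) and `params`.
#' @export
extract_feature_matrix <- function(epoch_set, params = complexity_params(),
                                   families = FEATURE_FAMILIES) {
  stopifnot(inherits(epoch_set, "mw_epoch_set"))
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  channels <- epoch_set$channel_labels
  fs <- epoch_set$sampling_rate
  desc <- do.call(rbind, lapply(families, family_descriptors,
                                channels = channels, params = params))
  n_ep <- length(epoch_set$epochs)
  values <- matrix(NA_real_, n_ep, nrow(desc))
  for (e in seq_len(n_ep)) {
    values[e, ] <- unlist(lapply(families, function(fam)
      epoch_family_features(epoch_set$epochs[[e]], fam, params, fs)))
  }
  colnames(values) <- paste(desc$family, desc$channel, desc$scale_or_band,
                            sep = "|")
  miss_frac <- rowMeans(is.na(values))
  keep <- miss_frac <= 0.20
  if (any(!keep))
    warning(sprintf("%d epoch(s) dropped (> 20%% missing features)",
                    sum(!keep)), call. = FALSE)
  structure(list(values = values[keep, , drop = FALSE],
                 descriptors = desc,
                 meta = epoch_set$meta[keep, , drop = FALSE],
                 params = params),
            class = "mw_features")
}

#' @export
print.mw_features <- function(x, ...) {
  cat(sprintf("<mw_features> %d epochs x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$descriptors$family), collapse = ", ")))
  invisible(x)
}

# Column indices of a family (optionally one scale or band, or one channel).
feature_columns <- function(features, family = NULL, scale_or_band = NULL,
                            channel = NULL) {
  d <- features$descriptors
  sel <- rep(TRUE, nrow(d))
  if (!is.null(family)) sel <- sel & d$family %in% family
  if (!is.null(scale_or_band)) sel <- sel & d$scale_or_band %in% scale_or_band
  if (!is.null(channel)) sel <- sel & d$channel %in% channel
  which(sel)
}
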