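# Probe-grouped cross-validation: folds partition probes, never windows, so
# overlapping windows from one probe can never straddle train and test.

#' Cross-validation configuration
#'
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats of the fold division (default 2).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param mrmr_k number of features kept by MRMR inside each training fold;
#'   `NULL` disables selection.
#' @param num_trees random forest size (default 100, the reference
#'   classifier library's default).
#' @param seed master seed; per-(participant, repeat, fold) streams are
#'   derived from it.
#' @export
cv_config <- function(n_folds = 10, n_repeats = 2, smote_k = 5,
                      mrmr_k = NULL, num_trees = 100, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
       smote_k = as.integer(smote_k), mrmr_k = mrmr_k,
       num_trees = as.integer(num_trees), seed = as.integer(seed))
}

# Label-stratified partition of probe indices into k folds.
stratified_partition <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Probe-grouped stratified fold assignments
#'
#' For each participant and repeat, the participant's labeled probes are
#' partitioned into `n_folds` label-stratified folds. A fold division whose
#' training split would miss a class is re-drawn (up to 10 times); if that
#' fails the participant is skipped with a warning.
#'
#' @param probes data.frame with columns `participant_id`, `probe_id`,
#'   `label` (`"MW"`/`"nonMW"`), one row per labeled probe.
#' @param cfg a [cv_config()].
#' @return data.frame with columns `participant_id`, `probe_id`, `label`,
#'   `rep`, `fold`.
#' @export
probe_grouped_folds <- function(probes, cfg = cv_config()) {
  stopifnot(all(c("participant_id", "probe_id", "label") %in% names(probes)))
  out <- NULL
  for (pid in unique(probes$participant_id)) {
    pp <- probes[probes$participant_id == pid, , drop = FALSE]
    if (nrow(pp) < cfg$n_folds) {
      warning(sprintf("participant %s skipped: fewer than %d labeled probes",
                      pid, cfg$n_folds), call. = FALSE)
      next
    }
    if (length(unique(pp$label)) < 2) {
      warning(sprintf("participant %s skipped: only one class present", pid),
              call. = FALSE)
      next
    }
    for (r in seq_len(cfg$n_repeats)) {
      fold <- NULL
      for (try in seq_len(10)) {
        fold_try <- with_local_seed(
          derive_seed(cfg$seed, pid, r, try),
          stratified_partition(pp$label, cfg$n_folds))
        ok <- all(vapply(seq_len(cfg$n_folds), function(f)
          length(unique(pp$label[fold_try != f])) == 2, logical(1)))
        if (ok) { fold <- fold_try; break }
      }
      if (is.null(fold)) {
        warning(sprintf(
          "participant %s skipped: no valid stratification after 10 tries", pid),
          call. = FALSE)
        next
      }
      out <- rbind(out, data.frame(participant_id = pid,
                                   probe_id = pp$probe_id,
                                   label = pp$label,
                                   rep = r, fold = fold,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(participant_id = character(), probe_id = character(),
                      label = character(), rep = integer(), fold = integer())
  out
}
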