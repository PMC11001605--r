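# Probe labeling and pre-probe window extraction with class-dependent
# augmentation: mind-wandering probes get 4 overlapping 10 s windows
# (2.5 s step, 75% overlap), on-task probes get 2 (5 s step, 50% overlap);
# evaluation always uses the single window ending at the probe.

#' Label a probe response
#'
#' Response 3 ("things unrelated to the task") is mind wandering; responses
#' 1 and 2 are non-MW. Probes answered with the lowest confidence rating (1)
#' are excluded regardless of the attention response.
#'
#' @param response attention response code(s) in 1..3.
#' @param confidence confidence code(s) in 1..3.
#' @return character vector in `{"MW", "nonMW", "excluded"}`.
#' @export
label_probe <- function(response, confidence) {
  if (!all(response %in% 1:3)) stop("response codes must be 1, 2 or 3")
  if (!all(confidence %in% 1:3)) stop("confidence codes must be 1, 2 or 3")
  out <- ifelse(response == 3, "MW", "nonMW")
  out[confidence == 1] <- "excluded"
  out
}

# Extract one window of `duration` seconds ending at `end_s`; NULL if it
# leaves the probe's block / the session, or touches a rejected interval.
slice_window <- function(session, end_s, duration, block_start, block_end) {
  start_s <- end_s - duration
  if (start_s < block_start - 1e-9 || end_s > block_end + 1e-9) return(NULL)
  if (overlaps_any(start_s, end_s, session$rejected_intervals)) return(NULL)
  fs <- session$sampling_rate
  i0 <- round(start_s * fs)
  nsamp <- round(duration * fs)
  if (i0 < 0 || i0 + nsamp > ncol(session$signal)) return(NULL)
  session$signal[, (i0 + 1):(i0 + nsamp), drop = FALSE]
}

probe_block_bounds <- function(session, time_s) {
  if (is.null(session$blocks))
    return(c(0, ncol(session$signal) / session$sampling_rate))
  b <- session$blocks[session$blocks$start_s <= time_s + 1e-9 &
                      time_s <= session$blocks$end_s + 1e-9, , drop = FALSE]
  if (nrow(b) == 0)
    return(c(0, ncol(session$signal) / session$sampling_rate))
  c(b$start_s[1], b$end_s[1])
}

#' Class-dependent augmentation windows for one probe
#'
#' MW probes yield up to 4 windows ending at `time - k * 2.5` s (k = 0..3);
#' non-MW probes up to 2 windows ending at `time - k * 5` s (k = 0..1), each
#' 10 s long. Windows that would precede the probe's block, leave the
#' session, or overlap a rejected interval are dropped with a warning.
#'
#' @param session a cleaned `mw_session`.
#' @param probe one row of the session's probe table (list or data.frame row
#'   with `time_s` and `probe_id`).
#' @param label `"MW"` or `"nonMW"`.
#' @param duration window length in seconds (default 10).
#' @return list of epochs, each a list with `data` (channels x samples),
#'   `label`, `probe_id`, `participant_id`, `offset` (seconds from window end
#'   to probe time). Possibly empty.
#' @export
augment_windows <- function(session, probe, label, duration = 10) {
  if (!label %in% c("MW", "nonMW")) stop("label must be 'MW' or 'nonMW'")
  offsets <- if (label == "MW") c(0, 2.5, 5, 7.5) else c(0, 5)
  bounds <- probe_block_bounds(session, probe$time_s)
  out <- list()
  dropped <- 0L
  for (off in offsets) {
    dat <- slice_window(session, probe$time_s - off, duration,
                        bounds[1], bounds[2])
    if (is.null(dat)) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- list(data = dat, label = label,
                                    probe_id = probe$probe_id,
                                    participant_id = session$participant_id,
                                    offset = off)
  }
  if (dropped > 0)
    warning(sprintf("probe %s: %d window(s) dropped (boundary or rejected interval)",
                    probe$probe_id, dropped), call. = FALSE)
  out
}

#' Evaluation window for one probe
#'
#' The single 10 s window ending exactly at the probe, used for every test
#' prediction regardless of class.
#'
#' @inheritParams augment_windows
#' @param label label to attach.
#' @return one epoch (as in [augment_windows()]) or `NULL` with a warning if
#'   there is no clean 10 s stretch before the probe.
#' @export
test_window <- function(session, probe, label, duration = 10) {
  bounds <- probe_block_bounds(session, probe$time_s)
  dat <- slice_window(session, probe$time_s, duration, bounds[1], bounds[2])
  if (is.null(dat)) {
    warning(sprintf("probe %s dropped from evaluation: no clean %g s window",
                    probe$probe_id, duration), call. = FALSE)
    return(NULL)
  }
  list(data = dat, label = label, probe_id = probe$probe_id,
       participant_id = session$participant_id, offset = 0)
}

#' Build the labeled epoch set of a cleaned session
#'
#' Labels all probes, drops excluded ones, and extracts every augmentation
#' window. Offset-0 windows double as the evaluation windows (`is_test`).
#'
#' @param session a cleaned `mw_session`.
#' @param duration window length in seconds (default 10).
#' @return object of class `mw_epoch_set`: list with `epochs` (list of
#'   channels x samples matrices) and `meta` (data.frame: participant_id,
#'   probe_id, label, offset, is_test).
#' @export
build_epoch_set <- function(session, duration = 10) {
  probes <- session$probes
  probes$label <- label_probe(probes$response, probes$confidence)
  probes <- probes[probes$label != "excluded", , drop = FALSE]
  epochs <- list()
  meta <- NULL
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, ]
    wins <- suppressWarnings(augment_windows(session, p, p$label, duration))
    for (w in wins) {
      epochs[[length(epochs) + 1L]] <- w$data
      meta <- rbind(meta, data.frame(
        participant_id = w$participant_id, probe_id = w$probe_id,
        label = w$label, offset = w$offset, is_test = w$offset == 0,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(epochs = epochs,
                 channel_labels = session$channel_labels,
                 sampling_rate = session$sampling_rate,
                 meta = if (is.null(meta)) {
                   data.frame(participant_id = character(), probe_id = character(),
                              label = character(), offset = numeric(),
                              is_test = logical())
                 } else meta),
            class = "mw_epoch_set")
}

#' Apply the participant-level inclusion rule
#'
#' Participants whose proportion of mind-wandering probes (after confidence
#' exclusion) is below 10% are removed. A proportion of exactly 10% is kept
#' (strict "below" reading).
#'
#' @param probe_labels data.frame with columns `participant_id` and `label`
#'   (`"MW"`/`"nonMW"`), one row per labeled probe.
#' @param min_mw_prop exclusion threshold (default 0.10).
#' @return list with `kept`, `removed` (participant ids) and `proportions`
#'   (named MW proportions).
#' @export
filter_participants <- function(probe_labels, min_mw_prop = 0.10) {
  if (nrow(probe_labels) == 0) stop("empty cohort")
  props <- tapply(probe_labels$label == "MW", probe_labels$participant_id, mean)
  removed <- names(props)[props < min_mw_prop]
  list(kept = setdiff(names(props), removed),
       removed = removed,
       proportions = props)
}
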