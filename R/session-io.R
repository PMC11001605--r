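# On-disk layout for sessions: per participant a float32 binary signal file
# (channel-major: channel 1's samples, then channel 2's, ...), a CSV event
# table, and a JSON sidecar with sampling rate and channel labels.

#' Write a session to the documented on-disk layout
#'
#' @param session an `mw_session`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$participant_id
  sig_path <- file.path(dir, paste0(id, "_signal.f32"))
  ev_path <- file.path(dir, paste0(id, "_events.csv"))
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  con <- file(sig_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(session$signal)), con, size = 4)
  ev <- session$probes[, c("probe_id", "time_s", "trigger", "response",
                           "confidence", "drowsiness")]
  utils::write.csv(ev, ev_path, row.names = FALSE)
  jsonlite::write_json(list(
    participant_id = id,
    sampling_rate = session$sampling_rate,
    n_channels = nrow(session$signal),
    n_samples = ncol(session$signal),
    channel_labels = session$channel_labels,
    blocks = session$blocks
  ), meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(signal = sig_path, events = ev_path, meta = meta_path))
}

#' Read a session from the on-disk layout
#'
#' Counterpart of [write_session()]. Signal values round-trip at float32
#' precision; event times and metadata round-trip exactly.
#'
#' @param dir directory containing the three files.
#' @param participant_id id used in the file names.
#' @return an `mw_session`.
#' @export
read_session <- function(dir, participant_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(participant_id, "_meta.json")),
                              simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(dir, paste0(participant_id, "_signal.f32")), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4)
  sig <- t(matrix(vals, nrow = meta$n_samples, ncol = meta$n_channels))
  ev <- utils::read.csv(file.path(dir, paste0(participant_id, "_events.csv")),
                        stringsAsFactors = FALSE)
  structure(list(
    signal = sig,
    sampling_rate = meta$sampling_rate,
    channel_labels = meta$channel_labels,
    probes = ev,
    blocks = as.data.frame(meta$blocks),
    heog = NULL,
    participant_id = meta$participant_id,
    rejected_intervals = NULL,
    preproc = list()
  ), class = "mw_session")
}
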