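#' Write a trial table as a BIDS-style events file
#'
#' Tab-separated with `onset` and `duration` in seconds followed by
#' `trial_type`, `stimulus_id`, `probe_match`, `response`, `correct`,
#' `block`.
#'
#' @param trials Trial table from [schedule_session()].
#' @param path Output `.tsv` path.
#' @param stim_duration_ms Stimulus duration written to `duration`.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(trials, path, stim_duration_ms = 1000) {
  df <- data.frame(
    onset = trials$onset_ms / 1000,
    duration = stim_duration_ms / 1000,
    trial_type = as.character(trials$category),
    stimulus_id = trials$stimulus_id,
    probe_match = trials$probe_match,
    response = trials$response,
    correct = trials$correct,
    block = trials$block)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events file back into a trial table
#'
#' @param path Path written by [write_events_tsv()].
#' @return A trial table `data.frame`.
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  data.frame(
    trial_index = seq_len(nrow(df)),
    block = df$block,
    category = factor(df$trial_type, levels = CATEGORIES),
    stimulus_id = df$stimulus_id,
    probe_match = as.logical(df$probe_match),
    iti_ms = NA_real_,
    onset_ms = df$onset * 1000,
    response = df$response,
    correct = as.logical(df$correct),
    stringsAsFactors = FALSE)
}

#' Write a continuous recording as float32 binary plus JSON sidecar
#'
#' Channels x samples stored sample-major as little-endian float32 in
#' `<prefix>_eeg.dat`; sampling rate, channel names and units go to
#' `<prefix>_eeg.json`.
#'
#' @param eeg Channels x samples matrix (uV).
#' @param fs_hz Sampling rate.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_eeg_bin <- function(eeg, fs_hz, prefix) {
  con <- file(paste0(prefix, "_eeg.dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(eeg), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(sampling_frequency_hz = fs_hz,
         n_channels = nrow(eeg), n_samples = ncol(eeg),
         channel_names = paste0("ch", seq_len(nrow(eeg))),
         units = "uV", layout = "channels x samples, column-major float32"),
    paste0(prefix, "_eeg.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_eeg_bin()]
#'
#' @param prefix Path prefix used at write time.
#' @return List with `eeg` (channels x samples) and `fs_hz`.
#' @export
read_eeg_bin <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_eeg.json"),
                              simplifyVector = TRUE)
  con <- file(paste0(prefix, "_eeg.dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 4, endian = "little")
  list(eeg = matrix(x, meta$n_channels, meta$n_samples),
       fs_hz = meta$sampling_frequency_hz)
}

#' Write a synthetic session to disk
#'
#' Events as BIDS-style TSV, the continuous recording as float32 binary
#' with JSON sidecar, and subject metadata as JSON.
#'
#' @param session A `synth_session`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- session$subject$subject_id
  prefix <- file.path(dir, id)
  write_events_tsv(session$trials, paste0(prefix, "_events.tsv"),
                   stim_duration_ms = 1000)
  write_eeg_bin(session$eeg, session$fs_hz, prefix)
  jsonlite::write_json(unclass(session$subject),
                       paste0(prefix, "_subject.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @param subject_id Subject identifier (file prefix).
#' @return A `synth_session`-shaped list (without planted patterns).
#' @export
read_session <- function(dir, subject_id) {
  prefix <- file.path(dir, subject_id)
  rec <- read_eeg_bin(prefix)
  subj <- jsonlite::read_json(paste0(prefix, "_subject.json"),
                              simplifyVector = TRUE)
  structure(
    list(eeg = rec$eeg, fs_hz = rec$fs_hz,
         trials = read_events_tsv(paste0(prefix, "_events.tsv")),
         subject = do.call(subject_spec, subj), patterns = NULL,
         windows = NULL),
    class = "synth_session")
}
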