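#' Preprocessing configuration
#'
#' Holds the cleaning rules applied to continuous recordings: target
#' sampling rate, zero-phase bandpass (second order, i.e. 12 dB/octave
#' per pass, applied forward and backward), epoch window relative to
#' stimulus onset, the absolute-amplitude artifact-rejection threshold,
#' and the subject-level inclusion rules (strictly more than
#' `min_trials` clean trials, behavioural accuracy strictly above
#' chance).
#'
#' @param fs_target_hz Target sampling rate after downsampling (500).
#' @param band_hz Bandpass edges in Hz, `c(1, 40)`.
#' @param epoch_window_ms Epoch span in ms relative to stimulus onset,
#'   half-open, `c(-300, 3000)`.
#' @param reject_uv Absolute rejection threshold in uV (150).
#' @param min_trials Minimum clean-trial count, exclusive bound (200).
#' @param behav_chance Behavioural chance level, exclusive bound (0.5).
#' @return A `preproc_config` object.
#' @export
preproc_config <- function(fs_target_hz = 500, band_hz = c(1, 40),
                           epoch_window_ms = c(-300, 3000),
                           reject_uv = 150, min_trials = 200,
                           behav_chance = 0.5) {
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2])
    config_error("band_hz must be an increasing positive pair")
  if (band_hz[2] >= fs_target_hz / 2)
    config_error("band upper edge must be below the target Nyquist rate")
  if (length(epoch_window_ms) != 2 || epoch_window_ms[1] > 0 ||
      epoch_window_ms[2] <= 0)
    config_error("epoch_window_ms must contain time 0")
  if (reject_uv <= 0)
    config_error("reject_uv must be positive")
  structure(
    list(fs_target_hz = as.numeric(fs_target_hz),
         band_hz = as.numeric(band_hz),
         epoch_window_ms = as.numeric(epoch_window_ms),
         reject_uv = as.numeric(reject_uv),
         min_trials = as.numeric(min_trials),
         behav_chance = as.numeric(behav_chance)),
    class = "preproc_config")
}

#' Downsample and zero-phase bandpass a continuous recording
#'
#' Downsamples to `cfg$fs_target_hz` (integer factor, with the
#' anti-aliasing lowpass of [signal::decimate()]), removes the DC offset
#' per channel, then applies a second-order Butterworth bandpass
#' forward and backward ([signal::filtfilt()]): 12 dB/octave roll-off
#' per pass and no phase shift.
#'
#' @param eeg Channels x samples matrix (uV).
#' @param fs_hz Input sampling rate.
#' @param cfg A [preproc_config()].
#' @return List with filtered `eeg` and the new `fs_hz`.
#' @export
bandpass_resample <- function(eeg, fs_hz, cfg = preproc_config()) {
  if (cfg$fs_target_hz > fs_hz)
    stop("fs_target_hz exceeds the recording rate; upsampling is not supported")
  if (fs_hz < 2 * cfg$band_hz[2])
    stop("recording rate below twice the band upper edge")
  q <- fs_hz / cfg$fs_target_hz
  if (abs(q - round(q)) > 1e-9)
    stop("fs_hz must be an integer multiple of fs_target_hz")
  q <- round(q)
  if (q > 1) {
    # zero-phase windowed-sinc anti-alias lowpass, then subsample
    h <- signal::fir1(60, 0.9 / q)
    half <- (length(h) - 1) / 2
    n <- ncol(eeg)
    eeg <- t(apply(eeg, 1, function(x) {
      xf <- stats::filter(c(rep(0, half), x, rep(0, half)), h, sides = 2)
      xf[(half + 1):(half + n)][seq(1, n, by = q)]
    }))
  }
  eeg <- eeg - rowMeans(eeg)
  bf <- signal::butter(2, cfg$band_hz / (cfg$fs_target_hz / 2), type = "pass")
  eeg <- t(apply(eeg, 1, function(x) signal::filtfilt(bf, x)))
  list(eeg = eeg, fs_hz = cfg$fs_target_hz)
}

#' Epoched EEG container
#'
#' Trials x channels x samples array with its time axis, per-trial
#' category labels, retained-trial metadata and subject metadata. The
#' time axis is half-open: it starts at `epoch_window_ms[1]` and stops
#' one sample short of the window end.
#'
#' @param data Trials x channels x samples numeric array (uV).
#' @param times_ms Sample-aligned time vector (ms relative to onset).
#' @param fs_hz Sampling rate.
#' @param labels Per-trial category factor.
#' @param trial_meta Trial-table rows of the retained trials.
#' @param subject_meta Optional [subject_spec()] (or list).
#' @param windows Optional named list of analysis windows (ms pairs).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, times_ms, fs_hz, labels, trial_meta,
                      subject_meta = NULL, windows = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels),
            dim(data)[3] == length(times_ms))
  structure(
    list(data = data, times_ms = times_ms, fs_hz = fs_hz,
         labels = factor(labels, levels = CATEGORIES),
         trial_meta = trial_meta, subject_meta = subject_meta,
         windows = windows),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs_hz))
  cat(sprintf("  time %g..%g ms; labels: %s\n", min(x$times_ms),
              max(x$times_ms),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param ep An [epoch_set()].
#' @return Integer trial count.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' Subset an epoch set by trial index
#' @param ep An [epoch_set()].
#' @param idx Integer or logical trial index.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(ep, idx) {
  epoch_set(ep$data[idx, , , drop = FALSE], ep$times_ms, ep$fs_hz,
            ep$labels[idx], ep$trial_meta[idx, , drop = FALSE],
            ep$subject_meta, ep$windows)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Extracts one epoch per scheduled trial over the half-open window
#' `cfg$epoch_window_ms` relative to stimulus onset. No baseline-mean
#' subtraction is applied here; demeaning happens at classification.
#' Trials whose window falls outside the recording are dropped with a
#' warning.
#'
#' @param eeg Channels x samples matrix.
#' @param fs_hz Sampling rate of `eeg`.
#' @param events Trial table with `onset_ms` and `category`.
#' @param cfg A [preproc_config()].
#' @param subject_meta Optional subject metadata to carry along.
#' @param windows Optional analysis-window list; defaults to the three
#'   canonical windows clipped to the epoch span.
#' @return An [epoch_set()].
#' @export
epoch_trials <- function(eeg, fs_hz, events, cfg = preproc_config(),
                         subject_meta = NULL, windows = NULL) {
  w <- cfg$epoch_window_ms
  n_samp <- round(diff(w) * fs_hz / 1000)
  times_ms <- w[1] + (seq_len(n_samp) - 1) * 1000 / fs_hz
  rel0 <- round(w[1] * fs_hz / 1000)
  n_rec <- ncol(eeg)
  starts <- round(events$onset_ms * fs_hz / 1000) + 1 + rel0
  ok <- starts >= 1 & (starts + n_samp - 1) <= n_rec
  if (any(!ok))
    warning(sprintf("%d trial(s) dropped: epoch window outside the recording",
                    sum(!ok)))
  events <- events[ok, , drop = FALSE]
  starts <- starts[ok]
  data <- array(0, dim = c(nrow(events), nrow(eeg), n_samp))
  for (i in seq_along(starts)) {
    data[i, , ] <- eeg[, starts[i]:(starts[i] + n_samp - 1)]
  }
  if (is.null(windows)) {
    full <- list(Baseline = c(-300, 0), Sensory = c(0, 1000),
                 Delay = c(1000, 3000))
    windows <- Filter(function(v) v[1] >= w[1] && v[2] <= w[2], full)
  }
  epoch_set(data, times_ms, fs_hz, events$category, events,
            subject_meta = subject_meta, windows = windows)
}

#' Remove trials exceeding the amplitude threshold
#'
#' Drops every trial with any sample exceeding `cfg$reject_uv` in
#' absolute value on any channel. The rejection log (trial indices and
#' offending channels) is attached as `attr(, "rejection")`.
#'
#' @param ep An [epoch_set()].
#' @param cfg A [preproc_config()].
#' @return The cleaned `epoch_set`.
#' @export
reject_artifacts <- function(ep, cfg = preproc_config()) {
  thr <- cfg$reject_uv
  nt <- n_trials(ep)
  peak <- apply(abs(ep$data), 1, max)
  bad <- which(peak > thr)
  log <- data.frame(trial = integer(0), channels = character(0))
  if (length(bad)) {
    ch_bad <- vapply(bad, function(i) {
      m <- apply(abs(ep$data[i, , , drop = FALSE])[1, , ], 1, max)
      paste(which(m > thr), collapse = ";")
    }, "")
    log <- data.frame(trial = bad, channels = ch_bad,
                      stringsAsFactors = FALSE)
  }
  out <- if (length(bad)) subset_epochs(ep, -bad) else ep
  attr(out, "rejection") <- log
  attr(out, "n_rejected") <- length(bad)
  out
}

#' Score behavioural accuracy over a trial table
#'
#' Proportion of correct responses over all trials; missing responses
#' count as incorrect.
#'
#' @param trials Trial table with a `correct` column.
#' @return Accuracy in `[0, 1]`.
#' @export
score_behavior <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0)
    stop("cannot score behaviour on an empty trial table")
  mean(trials$correct %in% TRUE)
}

#' Apply the subject-level exclusion rules
#'
#' A subject is excluded iff behavioural accuracy is at or below chance
#' (`<= behav_chance`) or the clean-trial count is not strictly above
#' `min_trials`. Returns the retained subjects and a per-subject report.
#'
#' @param subjects List of [epoch_set()]s whose `subject_meta` carries
#'   `behavioral_accuracy_observed` (set by [preprocess_subject()]).
#' @param cfg A [preproc_config()].
#' @return List with `retained` (epoch sets) and `report` (data frame
#'   with subject, trial count, accuracy, exclusion flag and reason).
#' @export
apply_exclusions <- function(subjects, cfg = preproc_config()) {
  rows <- lapply(subjects, function(ep) {
    acc <- ep$subject_meta$behavioral_accuracy_observed
    nt <- n_trials(ep)
    reason <- c(
      if (acc <= cfg$behav_chance) "behavioral accuracy at or below chance",
      if (nt <= cfg$min_trials) sprintf("only %d clean trials (need > %d)",
                                        nt, cfg$min_trials))
    data.frame(subject_id = ep$subject_meta$subject_id,
               n_trials = nt, behavioral_accuracy = acc,
               excluded = length(reason) > 0,
               reason = paste(reason, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  retained <- subjects[!report$excluded]
  if (length(retained) == 0)
    stop("all subjects excluded; group-level analysis undefined")
  list(retained = retained, report = report)
}

#' Run the full preprocessing chain on one synthetic session
#'
#' Filter/resample, epoch, reject artifacts, and score behaviour; the
#' behavioural score is stored in the epoch set's `subject_meta` for
#' [apply_exclusions()].
#'
#' @param session A `synth_session` from [synthesize_subject()].
#' @param cfg A [preproc_config()].
#' @return A cleaned [epoch_set()].
#' @export
preprocess_subject <- function(session, cfg = preproc_config()) {
  flt <- bandpass_resample(session$eeg, session$fs_hz, cfg)
  ep <- epoch_trials(flt$eeg, flt$fs_hz, session$trials, cfg,
                     subject_meta = session$subject,
                     windows = session$windows)
  ep <- reject_artifacts(ep, cfg)
  ep$subject_meta$behavioral_accuracy_observed <-
    score_behavior(session$trials)
  ep
}
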