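#' Session configuration for the delayed-recognition task
#'
#' Describes one synthetic recording session of the single-item
#' delayed-recognition game: three stimulus categories (visual, spatial,
#' verbal), a jittered inter-trial interval, a 1-s Sensory (encoding)
#' period, a 2-s Delay (maintenance) period, then probe and response
#' periods. Defaults reproduce the study design: 128 trials per category
#' (384 in total), ITI jittered 800--1200 ms in 50-ms steps, probe
#' matching the memorandum on exactly half of the trials, 64 channels.
#'
#' @param n_trials_per_category Trials per category (default 128).
#' @param iti_range_ms Inclusive ITI jitter range in ms, `c(800, 1200)`.
#' @param iti_step_ms Jitter grid step in ms (50).
#' @param sensory_ms Stimulus presentation duration (1000).
#' @param delay_ms Retention interval duration (2000).
#' @param probe_ms Probe presentation duration (1000).
#' @param response_ms Maximum response window (2000).
#' @param probe_match_prob Probability that the probe matches the
#'   memorandum; enforced exactly per category (0.5).
#' @param n_channels Number of EEG channels (64).
#' @param fs_raw_hz Synthesis sampling rate in Hz (1000).
#' @return A `session_config` object (list).
#' @export
session_config <- function(n_trials_per_category = 128,
                           iti_range_ms = c(800, 1200),
                           iti_step_ms = 50,
                           sensory_ms = 1000,
                           delay_ms = 2000,
                           probe_ms = 1000,
                           response_ms = 2000,
                           probe_match_prob = 0.5,
                           n_channels = 64,
                           fs_raw_hz = 1000) {
  if (!is_count(n_trials_per_category))
    config_error("n_trials_per_category must be a positive integer")
  if (length(iti_range_ms) != 2 || iti_range_ms[1] > iti_range_ms[2] ||
      any(iti_range_ms <= 0))
    config_error("iti_range_ms must be an increasing positive pair")
  if (!is_count(iti_step_ms))
    config_error("iti_step_ms must be a positive integer")
  if ((iti_range_ms[2] - iti_range_ms[1]) %% iti_step_ms != 0)
    config_error("ITI range width must be divisible by iti_step_ms")
  for (nm in c("sensory_ms", "delay_ms", "probe_ms", "response_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      config_error("%s must be a positive duration", nm)
  }
  if (!is_prob(probe_match_prob))
    config_error("probe_match_prob must be in [0, 1]")
  if (!is_count(n_channels, min = 2))
    config_error("n_channels must be an integer >= 2")
  if (!is_count(fs_raw_hz, min = 1))
    config_error("fs_raw_hz must be a positive sampling rate")
  structure(
    list(n_trials_per_category = as.integer(n_trials_per_category),
         iti_range_ms = as.numeric(iti_range_ms),
         iti_step_ms = as.numeric(iti_step_ms),
         sensory_ms = as.numeric(sensory_ms),
         delay_ms = as.numeric(delay_ms),
         probe_ms = as.numeric(probe_ms),
         response_ms = as.numeric(response_ms),
         probe_match_prob = probe_match_prob,
         n_channels = as.integer(n_channels),
         fs_raw_hz = as.numeric(fs_raw_hz)),
    class = "session_config")
}

#' Forward signal model for synthetic category-specific EEG patterns
#'
#' The generator plants, for each category, a fixed unit-norm spatial
#' pattern across channels, scaled by an amplitude envelope: a constant
#' `amp_sensory` while the stimulus is on screen, then an exponential
#' decay with time constant `delay_decay_tau_ms` through the retention
#' interval (the maintained trace persists attenuated). Visual and
#' spatial patterns are constructed to be more mutually similar (cosine
#' `pattern_similarity_vs`) than either is to the verbal pattern
#' (`pattern_similarity_other`), mirroring the domain structure of
#' classical working-memory theory. Background activity is spatially
#' independent 1/f ("pink") noise; high-amplitude square-pulse artifacts
#' can be injected on a per-trial basis.
#'
#' @param amp_sensory Pattern amplitude during the Sensory period (uV).
#' @param delay_decay_tau_ms Exponential decay time constant of the
#'   pattern amplitude after stimulus offset (ms).
#' @param pattern_similarity_vs Cosine similarity between the visual and
#'   spatial patterns (default 0.6).
#' @param pattern_similarity_other Cosine similarity of the verbal
#'   pattern to each of the other two (default 0).
#' @param noise_pink_exponent Spectral slope alpha of the 1/f^alpha
#'   background noise (default 1).
#' @param noise_floor_hz Frequency below which the background spectrum
#'   flattens (default 0.1 Hz); amplifier coupling and electrode
#'   potentials bound real drift power, and unbounded 1/f drift would
#'   dominate a continuous session.
#' @param noise_sd Per-channel noise standard deviation (uV).
#' @param subject_snr_sd Between-subject log-normal spread of the SNR
#'   multiplier.
#' @param artifact_rate Probability that a trial receives an injected
#'   artifact pulse.
#' @param artifact_amp Artifact pulse amplitude (uV, default 200).
#' @param rotate_at_offset If `TRUE`, the Delay period carries an
#'   independent set of category patterns (drawn orthogonal to the
#'   Sensory patterns) instead of the decaying Sensory patterns; used to
#'   emulate a representational change at stimulus offset.
#' @return A `signal_model` object (list).
#' @export
signal_model <- function(amp_sensory = 3,
                         delay_decay_tau_ms = 800,
                         pattern_similarity_vs = 0.6,
                         pattern_similarity_other = 0,
                         noise_pink_exponent = 1,
                         noise_floor_hz = 0.1,
                         noise_sd = 10,
                         subject_snr_sd = 0.3,
                         artifact_rate = 0.02,
                         artifact_amp = 200,
                         rotate_at_offset = FALSE) {
  if (!is.numeric(amp_sensory) || amp_sensory < 0)
    config_error("amp_sensory must be >= 0")
  if (!is.numeric(delay_decay_tau_ms) || delay_decay_tau_ms <= 0)
    config_error("delay_decay_tau_ms must be > 0")
  for (s in c(pattern_similarity_vs, pattern_similarity_other)) {
    if (!is.numeric(s) || abs(s) > 1)
      config_error("pattern similarities must lie in [-1, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0)
    config_error("noise_sd must be >= 0")
  if (!is_prob(artifact_rate))
    config_error("artifact_rate must be in [0, 1]")
  structure(
    list(amp_sensory = amp_sensory,
         delay_decay_tau_ms = delay_decay_tau_ms,
         pattern_similarity_vs = pattern_similarity_vs,
         pattern_similarity_other = pattern_similarity_other,
         noise_pink_exponent = noise_pink_exponent,
         noise_floor_hz = noise_floor_hz,
         noise_sd = noise_sd,
         subject_snr_sd = subject_snr_sd,
         artifact_rate = artifact_rate,
         artifact_amp = artifact_amp,
         rotate_at_offset = isTRUE(rotate_at_offset)),
    class = "signal_model")
}

#' Subject specification
#'
#' @param subject_id Subject identifier string.
#' @param age_months Age in months (study range 84--152, i.e. 7;0--12;8).
#' @param snr_multiplier Positive multiplicative SNR factor for this
#'   subject.
#' @param behavioral_accuracy Probability of a correct probe response.
#' @return A `subject_spec` object (list).
#' @export
subject_spec <- function(subject_id, age_months = 115,
                         snr_multiplier = 1, behavioral_accuracy = 0.9) {
  if (!is_prob(behavioral_accuracy))
    config_error("behavioral_accuracy must be in [0, 1]")
  if (!is.numeric(snr_multiplier) || snr_multiplier <= 0)
    config_error("snr_multiplier must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         age_months = as.numeric(age_months),
         snr_multiplier = snr_multiplier,
         behavioral_accuracy = behavioral_accuracy),
    class = "subject_spec")
}

trial_duration_ms <- function(cfg, iti_ms) {
  iti_ms + cfg$sensory_ms + cfg$delay_ms + cfg$probe_ms + cfg$response_ms
}

#' Build a randomized trial schedule for one session
#'
#' Draws a seeded schedule with the design's exact constraints: equal
#' trial counts per category, categories randomly intermixed (no
#' blocking), exactly half probe-match trials within each category, ITIs
#' drawn uniformly from the permitted jitter grid, and trials partitioned
#' in temporal order into 8 equal blocks (self-timed break points).
#'
#' @param cfg A [session_config()].
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG.
#' @return A trial table (`data.frame`) with columns `trial_index`,
#'   `block`, `category`, `stimulus_id`, `probe_match`, `iti_ms`,
#'   `onset_ms`, `response`, `correct`.
#' @export
schedule_session <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "session_config"))
  n_cat <- cfg$n_trials_per_category
  n <- 3L * n_cat
  with_seed(seed, {
    category <- sample(rep(CATEGORIES, each = n_cat))
    # exact probe-match balance within each category
    n_match <- round(cfg$probe_match_prob * n_cat)
    probe_match <- logical(n)
    stimulus_id <- integer(n)
    for (cat in CATEGORIES) {
      idx <- which(category == cat)
      flags <- sample(c(rep(TRUE, n_match), rep(FALSE, n_cat - n_match)))
      probe_match[idx] <- flags
      stimulus_id[idx] <- sample.int(16L, n_cat, replace = TRUE)
    }
    grid <- seq(cfg$iti_range_ms[1], cfg$iti_range_ms[2], by = cfg$iti_step_ms)
    iti_ms <- sample(grid, n, replace = TRUE)
    # stimulus onset = end of the trial's ITI
    dur <- trial_duration_ms(cfg, iti_ms)
    onset_ms <- cumsum(c(0, dur[-n])) + iti_ms
    # 8 equal blocks in temporal order
    bounds <- round(seq(0, n, length.out = 9))
    block <- rep(seq_len(8), times = diff(bounds))
    data.frame(
      trial_index = seq_len(n),
      block = block,
      category = factor(category, levels = CATEGORIES),
      stimulus_id = stimulus_id,
      probe_match = probe_match,
      iti_ms = iti_ms,
      onset_ms = onset_ms,
      response = NA_character_,
      correct = NA,
      stringsAsFactors = FALSE)
  })
}

#' Construct category spatial patterns with a prescribed Gram matrix
#'
#' Builds three unit-norm channel vectors (visual, spatial, verbal) whose
#' pairwise cosine similarities exactly reproduce the requested values,
#' by mapping a random orthonormal basis through a square root of the
#' 3x3 Gram matrix. The construction is exact (up to floating point), not
#' sampled-and-checked.
#'
#' @param n_channels Number of channels.
#' @param similarity_vs Cosine between the visual and spatial patterns.
#' @param similarity_other Cosine of the verbal pattern to each other.
#' @param seed Integer seed for the random basis.
#' @return A 3 x n_channels matrix with rows named by category.
#' @export
make_patterns <- function(n_channels, similarity_vs = 0.6,
                          similarity_other = 0, seed = 1) {
  if (abs(similarity_vs) > 1 || abs(similarity_other) > 1)
    config_error("pattern similarities must lie in [-1, 1]")
  G <- matrix(c(1, similarity_vs, similarity_other,
                similarity_vs, 1, similarity_other,
                similarity_other, similarity_other, 1), 3, 3)
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-10)
    config_error(
      "requested similarity triple is infeasible (Gram matrix not positive semidefinite)")
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  basis <- with_seed(seed, {
    # seed = NULL draws from the ambient RNG
    q <- qr.Q(qr(matrix(rnorm(n_channels * 3), n_channels, 3)))
    t(q)  # 3 x n_channels orthonormal rows
  })
  P <- L %*% basis
  rownames(P) <- CATEGORIES
  P
}

#' Generate spatially independent 1/f background noise
#'
#' Shapes white Gaussian noise in the frequency domain so each channel's
#' power spectrum follows 1/f^alpha, then rescales every channel to the
#' requested standard deviation. When `fs_hz` and `floor_hz` are given,
#' the spectrum is flattened below `floor_hz`: physical recordings do
#' not carry unbounded drift power, because amplifier coupling and
#' electrode half-cell potentials bound the slowest fluctuations.
#'
#' @param n_channels Number of channels.
#' @param n_samples Number of samples per channel.
#' @param exponent Spectral slope alpha (1 = classic pink noise).
#' @param sd Target per-channel standard deviation (uV).
#' @param seed Optional seed; `NULL` uses the ambient RNG.
#' @param fs_hz Optional sampling rate, required for `floor_hz`.
#' @param floor_hz Frequency below which the spectrum is flat (0 =
#'   unbounded 1/f).
#' @return A n_channels x n_samples matrix.
#' @export
pink_noise <- function(n_channels, n_samples, exponent = 1, sd = 1,
                       seed = NULL, fs_hz = NULL, floor_hz = 0) {
  with_seed(seed, {
    if (sd == 0) return(matrix(0, n_channels, n_samples))
    nfft <- nextn(n_samples, c(2, 3, 5))
    f <- c(0, seq_len(nfft - 1))
    f <- pmin(f, nfft - f)          # two-sided frequency index
    if (floor_hz > 0 && !is.null(fs_hz)) {
      f_floor <- floor_hz * nfft / fs_hz
      f <- pmax(f, f_floor)
    }
    g <- c(0, f[-1]^(-exponent / 2))
    out <- matrix(0, n_channels, n_samples)
    # draw the spectrum directly (circular Gaussian per bin) and invert;
    # channels are processed in chunks to bound peak memory
    chunk <- max(1L, floor(6e6 / nfft))
    done <- 0L
    while (done < n_channels) {
      m <- min(chunk, n_channels - done)
      Z <- matrix(complex(real = rnorm(nfft * m),
                          imaginary = rnorm(nfft * m)), nfft, m) * g
      x <- Re(mvfft(Z, inverse = TRUE))[seq_len(n_samples), , drop = FALSE]
      n <- nrow(x)
      s <- sqrt(pmax(colSums(x^2) - colSums(x)^2 / n, 0) / (n - 1))
      x <- sweep(x, 2, ifelse(s > 0, s / sd, 1), "/")
      out[done + seq_len(m), ] <- t(x)
      done <- done + m
    }
    out
  })
}

# Amplitude envelope over epoch time (ms relative to stimulus onset):
# amp during [0, sensory), amp * exp(-(t - sensory)/tau) during
# [sensory, sensory + delay), 0 elsewhere.
signal_envelope <- function(t_ms, cfg, model) {
  env <- numeric(length(t_ms))
  sens <- t_ms >= 0 & t_ms < cfg$sensory_ms
  del <- t_ms >= cfg$sensory_ms & t_ms < cfg$sensory_ms + cfg$delay_ms
  env[sens] <- model$amp_sensory
  env[del] <- model$amp_sensory *
    exp(-(t_ms[del] - cfg$sensory_ms) / model$delay_decay_tau_ms)
  env
}

# Delay-period patterns: either the (decaying) Sensory patterns, or an
# independent set orthogonalized against them when rotate_at_offset.
delay_patterns <- function(patterns, model, n_channels, seed) {
  if (!model$rotate_at_offset) return(patterns)
  P2 <- make_patterns(n_channels, model$pattern_similarity_vs,
                      model$pattern_similarity_other, seed = seed)
  # project out the Sensory pattern span, renormalize rows
  B <- qr.Q(qr(t(patterns)))
  P2 <- P2 - (P2 %*% B) %*% t(B)
  P2 / sqrt(rowSums(P2^2))
}

draw_responses <- function(trials, behavioral_accuracy) {
  n <- nrow(trials)
  correct <- runif(n) < behavioral_accuracy
  truth <- ifelse(trials$probe_match, "k", "d")
  other <- ifelse(trials$probe_match, "d", "k")
  trials$response <- ifelse(correct, truth, other)
  trials$correct <- correct
  trials
}

inject_artifact_trials <- function(trials, model) {
  trials$artifact <- runif(nrow(trials)) < model$artifact_rate
  trials
}

#' Synthesize one subject's continuous EEG recording
#'
#' Produces a continuous multichannel signal at `cfg$fs_raw_hz`: 1/f
#' background noise plus, for every trial, the trial category's spatial
#' pattern scaled by the amplitude envelope (constant through the Sensory
#' period, exponentially decaying through the Delay period) and by the
#' subject's SNR multiplier. Artifact trials receive a +/-`artifact_amp`
#' 100-ms square pulse on a small random channel subset within the epoch
#' span. Behavioural responses are drawn Bernoulli per trial.
#'
#' @param cfg A [session_config()].
#' @param model A [signal_model()].
#' @param subj A [subject_spec()].
#' @param seed Integer seed.
#' @return A `synth_session`: list with `eeg` (channels x samples, uV),
#'   `fs_hz`, `trials` (trial table incl. responses and an `artifact`
#'   flag), `subject`, and `patterns`.
#' @export
synthesize_subject <- function(cfg, model, subj = subject_spec("s01"),
                               seed = 1) {
  stopifnot(inherits(cfg, "session_config"), inherits(model, "signal_model"))
  # one sequential RNG stream per subject: drawing the schedule, noise,
  # patterns, artifacts and behaviour from fixed-offset derived seeds
  # risks correlated streams
  with_seed(seed, {
    trials <- schedule_session(cfg, seed = NULL)
    fs <- cfg$fs_raw_hz
    n_trials <- nrow(trials)
    total_ms <- trials$onset_ms[n_trials] +
      trial_duration_ms(cfg, 0) + 1000  # 1 s tail padding
    n_samp <- ceiling(total_ms * fs / 1000)
    eeg <- pink_noise(cfg$n_channels, n_samp, model$noise_pink_exponent,
                      model$noise_sd, seed = NULL, fs_hz = fs,
                      floor_hz = model$noise_floor_hz)
    patterns <- make_patterns(cfg$n_channels, model$pattern_similarity_vs,
                              model$pattern_similarity_other, seed = NULL)
    pat_delay <- delay_patterns(patterns, model, cfg$n_channels,
                                seed = NULL)
    amp <- model$amp_sensory * subj$snr_multiplier
    n_sig <- round((cfg$sensory_ms + cfg$delay_ms) * fs / 1000)
    t_ms <- (seq_len(n_sig) - 1) * 1000 / fs
    env <- signal_envelope(t_ms, cfg, model) / max(model$amp_sensory, 1e-12)
    sens_part <- t_ms < cfg$sensory_ms
    if (amp > 0) {
      for (i in seq_len(n_trials)) {
        o <- round(trials$onset_ms[i] * fs / 1000) + 1
        idx <- o:(o + n_sig - 1)
        cat <- as.character(trials$category[i])
        shape <- outer(patterns[cat, ], env * sens_part) +
          outer(pat_delay[cat, ], env * !sens_part)
        eeg[, idx] <- eeg[, idx] + amp * shape
      }
    }
    trials <- inject_artifact_trials(trials, model)
    trials <- draw_responses(trials, subj$behavioral_accuracy)
    if (any(trials$artifact)) {
      pulse_len <- round(0.1 * fs)  # 100 ms
      span_ms <- cfg$sensory_ms + cfg$delay_ms - 100
      for (i in which(trials$artifact)) {
        o <- round(trials$onset_ms[i] * fs / 1000) + 1
        start <- o + round(runif(1, 0, span_ms) * fs / 1000)
        chans <- sample.int(cfg$n_channels, sample.int(4, 1))
        sgn <- sample(c(-1, 1), 1)
        eeg[chans, start:(start + pulse_len - 1)] <-
          eeg[chans, start:(start + pulse_len - 1)] +
          sgn * model$artifact_amp
      }
    }
    structure(list(eeg = eeg, fs_hz = fs, trials = trials, subject = subj,
                   patterns = patterns, windows = default_windows(cfg)),
              class = "synth_session")
  })
}

#' Synthesize a subject directly at the epoch level
#'
#' Fast simulation path for calibration studies: generates the epoched
#' data an ideal preprocessing of [synthesize_subject()] output would
#' yield, without synthesizing the continuous recording (inter-trial
#' samples and filtering are skipped; epoch noise is drawn independently
#' per trial). The planted signal, artifact injection and behavioural
#' model are identical to the continuous path.
#'
#' @param cfg A [session_config()].
#' @param model A [signal_model()].
#' @param subj A [subject_spec()].
#' @param seed Integer seed.
#' @param fs_hz Epoch sampling rate (default 200; needs no resampling).
#' @param epoch_window_ms Epoch span relative to stimulus onset; default
#'   `c(-300, sensory + delay)`.
#' @return An [epoch_set()].
#' @export
synthesize_epochs <- function(cfg, model, subj = subject_spec("s01"),
                              seed = 1, fs_hz = 200,
                              epoch_window_ms = NULL) {
  stopifnot(inherits(cfg, "session_config"), inherits(model, "signal_model"))
  if (is.null(epoch_window_ms))
    epoch_window_ms <- c(-300, cfg$sensory_ms + cfg$delay_ms)
  # one sequential RNG stream per subject (see synthesize_subject)
  with_seed(seed, {
    trials <- schedule_session(cfg, seed = NULL)
    n_trials <- nrow(trials)
    n_ch <- cfg$n_channels
    n_samp <- round(diff(epoch_window_ms) * fs_hz / 1000)
    times_ms <- epoch_window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs_hz
    noise <- pink_noise(n_trials * n_ch, n_samp, model$noise_pink_exponent,
                        model$noise_sd, seed = NULL, fs_hz = fs_hz,
                        floor_hz = model$noise_floor_hz)
    data <- array(noise, dim = c(n_trials, n_ch, n_samp))
    patterns <- make_patterns(n_ch, model$pattern_similarity_vs,
                              model$pattern_similarity_other, seed = NULL)
    pat_delay <- delay_patterns(patterns, model, n_ch, seed = NULL)
    amp <- model$amp_sensory * subj$snr_multiplier
    if (amp > 0) {
      env <- signal_envelope(times_ms, cfg, model) /
        max(model$amp_sensory, 1e-12)
      sens_part <- times_ms >= 0 & times_ms < cfg$sensory_ms
      for (cat in CATEGORIES) {
        idx <- which(trials$category == cat)
        shape <- outer(patterns[cat, ], env * sens_part) +
          outer(pat_delay[cat, ], env * !sens_part)
        data[idx, , ] <- data[idx, , ] +
          rep(amp * shape, each = length(idx))
      }
    }
    trials <- inject_artifact_trials(trials, model)
    trials <- draw_responses(trials, subj$behavioral_accuracy)
    if (any(trials$artifact)) {
      pulse_len <- round(0.1 * fs_hz)
      post <- which(times_ms >= 0)
      for (i in which(trials$artifact)) {
        start <- sample(post[post <= n_samp - pulse_len], 1)
        chans <- sample.int(n_ch, sample.int(4, 1))
        sgn <- sample(c(-1, 1), 1)
        data[i, chans, start:(start + pulse_len - 1)] <-
          data[i, chans, start:(start + pulse_len - 1)] +
          sgn * model$artifact_amp
      }
    }
    epoch_set(data, times_ms, fs_hz, trials$category, trials,
              subject_meta = subj, windows = default_windows(cfg))
  })
}

# The three canonical analysis windows implied by a session config.
default_windows <- function(cfg) {
  list(Baseline = c(-300, 0),
       Sensory = c(0, cfg$sensory_ms),
       Delay = c(cfg$sensory_ms, cfg$sensory_ms + cfg$delay_ms))
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject ages (uniform over `age_range_months`) and SNR
#' multipliers (log-normal with spread `model$subject_snr_sd`, optionally
#' modulated linearly by age through `age_effect`, expressed as
#' proportional SNR change per year of age), then synthesizes each
#' subject with the per-subject seed `seed + index`.
#'
#' @param n_subjects Number of subjects.
#' @param cfg A [session_config()].
#' @param model A [signal_model()].
#' @param age_effect Proportional SNR change per year of age relative to
#'   the cohort mean age (default 0: decoding independent of age).
#' @param seed Master seed.
#' @param age_range_months Age range (default 84--152 months).
#' @param behavioral_accuracy Per-subject correct-response probability.
#' @param process Optional function applied to each `synth_session`
#'   immediately after synthesis (e.g. [preprocess_subject()]); its value
#'   is stored instead of the raw session, keeping memory bounded.
#' @return List of per-subject datasets (`synth_session`s or `process`
#'   outputs), with the cohort table in `attr(, "cohort")`.
#' @export
simulate_cohort <- function(n_subjects, cfg, model, age_effect = 0,
                            seed = 1, age_range_months = c(84, 152),
                            behavioral_accuracy = 0.9, process = NULL) {
  stopifnot(n_subjects >= 1)
  specs <- cohort_specs(n_subjects, model, age_effect, seed,
                        age_range_months, behavioral_accuracy)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ses <- synthesize_subject(cfg, model, specs[[i]], seed = seed + i)
    out[[i]] <- if (is.null(process)) ses else process(ses)
  }
  names(out) <- vapply(specs, `[[`, "", "subject_id")
  attr(out, "cohort") <- data.frame(
    subject_id = names(out),
    age_months = vapply(specs, `[[`, 0, "age_months"),
    snr_multiplier = vapply(specs, `[[`, 0, "snr_multiplier"))
  out
}

cohort_specs <- function(n_subjects, model, age_effect, seed,
                         age_range_months, behavioral_accuracy) {
  with_seed(derive_seed(seed, 0), {
    ages <- round(runif(n_subjects, age_range_months[1], age_range_months[2]))
    mult <- exp(rnorm(n_subjects, 0, model$subject_snr_sd))
    if (age_effect != 0) {
      mult <- mult * pmax(0.05, 1 + age_effect *
                            (ages - mean(age_range_months)) / 12)
    }
    lapply(seq_len(n_subjects), function(i)
      subject_spec(sprintf("s%02d", i), ages[i], mult[i],
                   behavioral_accuracy))
  })
}

#' Simulate a cohort and return clean epoch sets
#'
#' Convenience wrapper running the full per-subject chain
#' (synthesize, filter/resample, epoch, reject artifacts) or the
#' epoch-level fast path, keeping only each subject's cleaned
#' [epoch_set()] plus behavioural score.
#'
#' @inheritParams simulate_cohort
#' @param pcfg A [preproc_config()] (full path) or `NULL` for defaults.
#' @param method `"full"` (continuous synthesis + preprocessing) or
#'   `"direct"` (epoch-level synthesis + artifact rejection only).
#' @param fs_direct Sampling rate of the direct path (default 200 Hz).
#' @return List of `epoch_set`s with cohort table in `attr(, "cohort")`.
#' @export
cohort_epochs <- function(n_subjects, cfg, model, pcfg = NULL,
                          age_effect = 0, seed = 1,
                          age_range_months = c(84, 152),
                          behavioral_accuracy = 0.9,
                          method = c("direct", "full"),
                          fs_direct = 200) {
  method <- match.arg(method)
  if (is.null(pcfg)) {
    # the bandpass is never applied on the direct path; clip its upper
    # edge so low epoch rates pass the config validation
    pcfg <- preproc_config(
      fs_target_hz = if (method == "direct") fs_direct else 500,
      band_hz = c(1, min(40, 0.45 * if (method == "direct") fs_direct
                         else 500)),
      epoch_window_ms = c(-300, cfg$sensory_ms + cfg$delay_ms))
  }
  specs <- cohort_specs(n_subjects, model, age_effect, seed,
                        age_range_months, behavioral_accuracy)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    if (method == "full") {
      ses <- synthesize_subject(cfg, model, specs[[i]], seed = seed + i)
      out[[i]] <- preprocess_subject(ses, pcfg)
    } else {
      ep <- synthesize_epochs(cfg, model, specs[[i]], seed = seed + i,
                              fs_hz = fs_direct,
                              epoch_window_ms = pcfg$epoch_window_ms)
      ep$subject_meta$behavioral_accuracy_observed <-
        score_behavior(ep$trial_meta)
      out[[i]] <- reject_artifacts(ep, pcfg)
    }
  }
  names(out) <- vapply(specs, `[[`, "", "subject_id")
  attr(out, "cohort") <- data.frame(
    subject_id = names(out),
    age_months = vapply(specs, `[[`, 0, "age_months"),
    snr_multiplier = vapply(specs, `[[`, 0, "snr_multiplier"))
  out
}
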