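test_that("session schedule meets the design's exact count constraints", {
  tt <- schedule_session(session_config(), seed = 11)
  expect_equal(nrow(tt), 384)
  expect_true(all(table(tt$category) == 128))
  expect_true(all(tapply(tt$probe_match, tt$category, sum) == 64))
  expect_true(all(table(tt$block) == 48))
  # blocks partition trials in temporal order
  expect_true(all(diff(tt$block) >= 0))
  expect_true(all(diff(tt$onset_ms) > 0))
  expect_equal(length(unique(tt$stimulus_id)), 16)
})

test_that("minimal schedule keeps exact balance", {
  tt <- schedule_session(session_config(n_trials_per_category = 2), seed = 1)
  expect_equal(nrow(tt), 6)
  expect_true(all(table(tt$category) == 2))
  expect_true(all(tapply(tt$probe_match, tt$category, sum) == 1))
})

test_that("exact balance holds for every seed", {
  for (s in 1:8) {
    tt <- schedule_session(session_config(n_trials_per_category = 24),
                           seed = s)
    expect_true(all(table(tt$category) == 24))
    expect_true(all(tapply(tt$probe_match, tt$category, sum) == 12))
  }
})

test_that("ITIs come from the permitted jitter grid, uniformly", {
  grid <- seq(800, 1200, by = 50)
  itis <- unlist(lapply(1:27, function(s)
    schedule_session(session_config(), seed = 100 + s)$iti_ms))
  expect_gte(length(itis), 10000)
  expect_true(all(itis %in% grid))
  chi <- chisq.test(table(factor(itis, levels = grid)))
  expect_gt(chi$p.value, 0.01)
})

test_that("invalid session configurations are rejected", {
  expect_error(session_config(iti_range_ms = c(800, 1210)), "divisible")
  expect_error(session_config(n_trials_per_category = 0), "positive")
  expect_error(session_config(delay_ms = 0), "delay_ms")
})

test_that("pattern construction reproduces the requested Gram matrix", {
  P <- make_patterns(64, 0.6, 0, seed = 4)
  G <- matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3, 3)
  expect_lt(max(abs(P %*% t(P) - G)), 1e-6)
  expect_equal(unname(sqrt(rowSums(P^2))), rep(1, 3), tolerance = 1e-9)

  P0 <- make_patterns(32, 0, 0, seed = 2)
  expect_lt(max(abs(P0 %*% t(P0) - diag(3))), 1e-6)

  P1 <- make_patterns(32, 1, 0, seed = 2)
  expect_lt(max(abs(P1["visual", ] - P1["spatial", ])), 1e-6)
})

test_that("infeasible similarity triples raise a configuration error", {
  expect_error(make_patterns(16, -1, 0.9, seed = 1),
               "positive semidefinite")
  expect_error(make_patterns(16, 1.5, 0, seed = 1), "\\[-1, 1\\]")
})

test_that("noise-free synthesis plants exactly pattern times envelope", {
  cfg <- quick_cfg(n = 4, ch = 8, fs = 200)
  model <- signal_model(amp_sensory = 3, delay_decay_tau_ms = 800,
                        noise_sd = 0, artifact_rate = 0)
  ses <- synthesize_subject(cfg, model, subject_spec("s", snr_multiplier = 2),
                            seed = 5)
  tr <- ses$trials[1, ]
  o <- round(tr$onset_ms * 200 / 1000) + 1
  cat <- as.character(tr$category)
  # mid-Sensory sample: amplitude amp * snr
  expect_equal(ses$eeg[, o + 100], 6 * ses$patterns[cat, ],
               tolerance = 1e-9)
  # mid-Delay sample decays exponentially from stimulus offset
  t_del <- 500
  expect_equal(ses$eeg[, o + 200 + t_del / 5],
               6 * exp(-t_del / 800) * ses$patterns[cat, ],
               tolerance = 1e-9)
  # pre-onset baseline carries no signal
  expect_equal(max(abs(ses$eeg[, o - 10])), 0)
  # delay amplitude never exceeds the sensory amplitude
  expect_lte(max(abs(ses$eeg)), 6 + 1e-9)
})

test_that("zero-amplitude epochs decode at chance in every window", {
  # per-dataset null accuracy at this size spreads widely (sd ~ 0.09);
  # average several subjects to test the calibration of the mean
  acc <- sapply(1:6, function(i) {
    ep <- synthesize_epochs(quick_cfg(n = 40, ch = 16), null_model(),
                            subject_spec("s"), seed = 20 + i)
    vapply(decode_timeavg_all(ep, cv_scheme(n_iterations = 20,
                                            seed = derive_seed(77, i))),
           `[[`, 0, "mean_accuracy")
  })
  for (w in rownames(acc)) expect_lt(abs(mean(acc[w, ]) - 1 / 3), 0.1)
})

test_that("undamped strong signal decodes near ceiling", {
  model <- signal_model(amp_sensory = 25, delay_decay_tau_ms = 1e9,
                        artifact_rate = 0)
  ep <- synthesize_epochs(quick_cfg(n = 40, ch = 16), model,
                          subject_spec("s"), seed = 22)
  res <- decode_timeavg_all(ep, cv_scheme(n_iterations = 15, seed = 3))
  expect_gt(res$Sensory$mean_accuracy, 0.9)
  expect_gt(res$Delay$mean_accuracy, 0.9)
})

test_that("injected artifacts are flagged at the expected binomial rate", {
  cfg <- session_config(n_trials_per_category = 128, n_channels = 16,
                        fs_raw_hz = 200)
  model <- signal_model(amp_sensory = 0, artifact_rate = 0.1,
                        artifact_amp = 200, noise_sd = 1)
  ep <- synthesize_epochs(cfg, model, subject_spec("s"), seed = 31)
  clean <- reject_artifacts(ep, preproc_config(reject_uv = 150))
  n_rej <- attr(clean, "n_rejected")
  expected <- 384 * 0.1
  band <- 3 * sqrt(384 * 0.1 * 0.9)
  expect_true(abs(n_rej - expected) <= band)
  expect_equal(sort(attr(clean, "rejection")$trial),
               which(ep$trial_meta$artifact))
})

test_that("behavioural responses track the specified accuracy", {
  cfg <- quick_cfg(n = 128, ch = 4, fs = 100)
  accs <- vapply(1:6, function(i) {
    ep <- synthesize_epochs(cfg, null_model(),
                            subject_spec("s", behavioral_accuracy = 0.9),
                            seed = 40 + i)
    score_behavior(ep$trial_meta)
  }, 0)
  se <- sqrt(0.9 * 0.1 / 384)
  expect_lt(abs(mean(accs) - 0.9), 2 * se)
})

test_that("cohort simulation is reproducible and honours the SNR spread", {
  cfg <- quick_cfg(n = 5, ch = 4, fs = 100)
  model <- signal_model(subject_snr_sd = 0)
  co1 <- simulate_cohort(3, cfg, model, seed = 9)
  co2 <- simulate_cohort(3, cfg, model, seed = 9)
  expect_identical(attr(co1, "cohort"), attr(co2, "cohort"))
  expect_identical(co1[[2]]$eeg, co2[[2]]$eeg)
  expect_true(all(attr(co1, "cohort")$snr_multiplier == 1))
  tab <- attr(co1, "cohort")
  expect_true(all(tab$age_months >= 84 & tab$age_months <= 152))

  co3 <- simulate_cohort(12, cfg, signal_model(subject_snr_sd = 0.5),
                         seed = 9)
  expect_gt(stats::sd(log(attr(co3, "cohort")$snr_multiplier)), 0.1)
})

test_that("an age effect modulates SNR multipliers in the right direction", {
  cfg <- quick_cfg(n = 5, ch = 4, fs = 100)
  co <- simulate_cohort(40, cfg, signal_model(subject_snr_sd = 0),
                        age_effect = 0.3, seed = 13)
  tab <- attr(co, "cohort")
  expect_gt(cor(tab$age_months, tab$snr_multiplier), 0.9)
})
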