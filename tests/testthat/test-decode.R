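test_that("identical seeds reproduce bit-identical accuracy vectors", {
  ep <- synthesize_epochs(quick_cfg(n = 25, ch = 8, fs = 100),
                          signal_model(artifact_rate = 0),
                          subject_spec("s"), seed = 5)
  cv <- cv_scheme(n_iterations = 12, seed = 99)
  r1 <- decode_window(ep, c(0, 1000), cv, "Sensory")
  r2 <- decode_window(ep, c(0, 1000), cv, "Sensory")
  expect_identical(r1$per_iteration_accuracy, r2$per_iteration_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  r3 <- decode_window(ep, c(0, 1000), cv_scheme(n_iterations = 12, seed = 98),
                      "Sensory")
  expect_false(identical(r1$per_iteration_accuracy,
                         r3$per_iteration_accuracy))
})

test_that("decoding refuses windows with too few trials per class", {
  ep <- synthesize_epochs(quick_cfg(n = 8, ch = 4, fs = 100), null_model(),
                          subject_spec("s"), seed = 2)
  expect_error(decode_window(ep, c(0, 1000), cv_scheme(), "Sensory"),
               "window Sensory.*class 'visual'")
})

test_that("feature-shift invariance: adding a constant changes nothing", {
  set.seed(8)
  X <- matrix(rnorm(90 * 6), 90, 6)
  y <- rep(c("visual", "spatial", "verbal"), each = 30)
  cv <- cv_scheme(n_iterations = 10, seed = 3)
  r1 <- decode_features(X, y, cv)
  r2 <- decode_features(X + 7, y, cv)
  expect_equal(r1$per_iteration_accuracy, r2$per_iteration_accuracy,
               tolerance = 1e-12)
})

test_that("label shuffling brings decoding back to chance", {
  model <- signal_model(amp_sensory = 10, artifact_rate = 0)
  ep <- synthesize_epochs(quick_cfg(n = 40, ch = 16), model,
                          subject_spec("s"), seed = 12)
  X <- window_average(ep, c(0, 1000))
  cv <- cv_scheme(n_iterations = 20, seed = 4)
  r_true <- decode_features(X, ep$labels, cv)
  y_shuf <- with_seed(31, sample(ep$labels))
  r_null <- decode_features(X, y_shuf, cv)
  expect_gt(r_true$mean_accuracy, 0.8)
  expect_lt(abs(r_null$mean_accuracy - 1 / 3), 0.15)
})

test_that("window structure follows the envelope: Sensory > Delay > Baseline-at-chance", {
  accs <- sapply(1:3, function(i) {
    ep <- synthesize_epochs(session_config(n_trials_per_category = 60),
                            signal_model(artifact_rate = 0),
                            subject_spec("s"), seed = 300 + i)
    vapply(decode_timeavg_all(ep, cv_scheme(n_iterations = 20, seed = i)),
           `[[`, 0, "mean_accuracy")
  })
  m <- rowMeans(accs)
  expect_gt(m["Sensory"], m["Delay"])
  expect_gt(m["Delay"], 0.36)
  expect_lt(abs(m["Baseline"] - 1 / 3), 0.1)
})

test_that("instant decay leaves the Delay window at chance", {
  model <- signal_model(amp_sensory = 10, delay_decay_tau_ms = 1,
                        artifact_rate = 0)
  accs <- sapply(1:6, function(i) {
    ep <- synthesize_epochs(quick_cfg(n = 40, ch = 16), model,
                            subject_spec("s"), seed = 16 + i)
    r <- decode_timeavg_all(ep, cv_scheme(n_iterations = 20, seed = 6))
    c(sensory = r$Sensory$mean_accuracy, delay = r$Delay$mean_accuracy)
  })
  expect_true(all(accs["sensory", ] > 0.7))
  expect_lt(abs(mean(accs["delay", ]) - 1 / 3), 0.12)
})

test_that("null-cohort chance calibration has no systematic bias or heavy tail", {
  accs <- vapply(1:50, function(i) {
    ep <- synthesize_epochs(session_config(n_trials_per_category = 128),
                            null_model(), subject_spec("s"),
                            seed = 4000 + i, fs_hz = 100)
    decode_window(ep, c(-300, 0),
                  cv_scheme(n_iterations = 100,
                            seed = derive_seed(4321, i)),
                  "Baseline")$mean_accuracy
  }, 0)
  # mean within the 0.01 calibration budget plus the replicate's own
  # sampling allowance (per-subject null spread is ~0.05 here)
  expect_lt(abs(mean(accs) - 1 / 3),
            0.01 + 2 * stats::sd(accs) / sqrt(50))
  # no heavy upper tail: the extreme subject stays within a Gaussian
  # envelope of the cohort spread
  expect_lt(max(accs), 1 / 3 + 4 * stats::sd(accs))
})

test_that("block split yields two equal halves that decode comparably", {
  cfg <- session_config(n_trials_per_category = 128, n_channels = 16,
                        fs_raw_hz = 100)
  ep <- synthesize_epochs(cfg, signal_model(artifact_rate = 0),
                          subject_spec("s"), seed = 23, fs_hz = 100)
  halves <- split_half_decode(ep, cv_scheme(n_iterations = 15, seed = 2))
  expect_equal(nrow(halves$early$Sensory$confusion), 3)
  n_early <- sum(ep$trial_meta$block <= 4)
  expect_equal(n_early, 192)
  expect_equal(n_trials(ep) - n_early, 192)
  d <- abs(halves$early$Sensory$mean_accuracy -
             halves$late$Sensory$mean_accuracy)
  expect_lt(d, 0.25)               # identically distributed halves
})

test_that("cross-decoding transfers when patterns are shared, not otherwise", {
  cfg <- quick_cfg(n = 40, ch = 64)
  model <- signal_model(amp_sensory = 10, artifact_rate = 0)
  ep1 <- synthesize_epochs(cfg, model, subject_spec("s1"), seed = 41)
  cv <- cv_scheme(n_iterations = 15, seed = 3)
  same <- cross_decode(ep1, ep1, cv, windows = list(Sensory = c(0, 1000)))
  expect_gt(same$Sensory$mean_accuracy, 0.8)

  # an independently seeded subject has different (near-orthogonal) patterns
  ep2 <- synthesize_epochs(cfg, model, subject_spec("s2"), seed = 4100)
  other <- cross_decode(ep1, ep2, cv, windows = list(Sensory = c(0, 1000)))
  expect_lt(abs(other$Sensory$mean_accuracy - 1 / 3), 0.15)

  ep3 <- synthesize_epochs(quick_cfg(n = 40, ch = 8), model,
                           subject_spec("s3"), seed = 43)
  expect_error(cross_decode(ep1, ep3, cv), "montage")
})

test_that("gen-matrix diagonal matches independently computed per-bin decoding", {
  cfg <- session_config(n_trials_per_category = 45, sensory_ms = 500,
                        delay_ms = 1000, n_channels = 16, fs_raw_hz = 200)
  model <- signal_model(amp_sensory = 6, delay_decay_tau_ms = 400,
                        artifact_rate = 0)
  ep <- synthesize_epochs(cfg, model, subject_spec("s"), seed = 51)
  cv <- cv_scheme(n_iterations = 15, seed = 7)
  gm <- temporal_generalization(ep, 50, cv)
  nb <- length(gm$times_ms)
  per_bin <- vapply(seq_len(nb), function(b) {
    w0 <- ep$times_ms[1] + (b - 1) * 50
    decode_window(ep, c(w0, w0 + 50), cv)$mean_accuracy
  }, 0)
  expect_gt(cor(diag(gm$accuracy), per_bin), 0.9)
})

test_that("20-ms and 50-ms generalization agree on a common coarse grid", {
  cfg <- session_config(n_trials_per_category = 45, sensory_ms = 500,
                        delay_ms = 1000, n_channels = 16, fs_raw_hz = 200)
  model <- signal_model(amp_sensory = 25, delay_decay_tau_ms = 1e9,
                        artifact_rate = 0)
  ep <- synthesize_epochs(cfg, model, subject_spec("s"), seed = 52,
                          epoch_window_ms = c(-300, 1500))
  cv <- cv_scheme(n_iterations = 25, seed = 9)
  g50 <- temporal_generalization(ep, 50, cv)
  g20 <- temporal_generalization(ep, 20, cv)
  # block-average both onto the shared 100-ms grid
  coarse <- function(gm, f) {
    nb <- (length(gm$times_ms) %/% f) * f
    a <- gm$accuracy[1:nb, 1:nb]
    g <- rep(seq_len(nb / f), each = f)
    rowsum(t(rowsum(a, g)), g) / f^2
  }
  a50 <- coarse(g50, 2)
  a20 <- coarse(g20, 5)
  # compare where the signal lives; pre-stimulus cells in both matrices
  # are chance-level noise whose per-dataset fluctuations dominate
  post <- seq(4, nrow(a50))        # 100-ms blocks fully after onset
  expect_lt(max(abs(a50[post, post] - a20[post, post])), 0.05)
  base <- 1:3
  expect_lt(max(abs(rowMeans(a50[base, post]) -
                      rowMeans(a20[base, post]))), 0.1)
})
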