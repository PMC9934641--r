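test_that("bandpass removes sub-band drift and preserves passband tones", {
  pc <- preproc_config()
  t <- seq(1 / 1000, 10, by = 1 / 1000)
  slow <- matrix(sin(2 * pi * 0.1 * t), 1)
  mid <- matrix(sin(2 * pi * 10 * t), 1)
  f_slow <- bandpass_resample(slow, 1000, pc)
  f_mid <- bandpass_resample(mid, 1000, pc)
  # length contract: 10 s at 1000 Hz -> 5000 samples at 500 Hz
  expect_equal(ncol(f_slow$eeg), 5000)
  expect_equal(f_slow$fs_hz, 500)
  # 0.1 Hz attenuated by at least 90 %
  expect_lt(max(abs(f_slow$eeg)), 0.1)
  # 10 Hz preserved within 5 % away from the edges
  core <- f_mid$eeg[1, 1000:4000]
  expect_lt(abs(max(abs(core)) - 1), 0.05)
  # zero phase: filtered peaks align with the input peaks
  x_ds <- mid[1, seq(1, 10000, 2)]
  peak_in <- 1000 + which.max(x_ds[1000:1100])
  peak_out <- 1000 + which.max(f_mid$eeg[1, 1000:1100])
  expect_lte(abs(peak_in - peak_out), 1)
})

test_that("upsampling and non-integer decimation are refused", {
  pc <- preproc_config(fs_target_hz = 500)
  x <- matrix(rnorm(400), 1)
  expect_error(bandpass_resample(x, 400, pc), "upsampling")
  expect_error(bandpass_resample(x, 750, pc), "integer multiple")
})

test_that("epoching honours the sample-count contract and onsets", {
  cfg <- preproc_config()
  events <- schedule_session(session_config(), seed = 2)
  n_rec <- ceiling((max(events$onset_ms) + 7000) * 500 / 1000)
  eeg <- matrix(0, 4, n_rec)
  ep <- epoch_trials(eeg, 500, events, cfg)
  expect_equal(dim(ep$data), c(384, 4, 1650))
  expect_equal(ep$times_ms[1], -300)
  expect_equal(ep$times_ms[1650], 3000 - 2)  # half-open window
  expect_true(all(ep$data == 0))
  expect_equal(as.character(ep$labels), as.character(events$category))
})

test_that("epochs that do not fit inside the recording are dropped", {
  cfg <- preproc_config()
  events <- data.frame(onset_ms = 100, category = "visual")
  eeg <- matrix(rnorm(4 * 5000), 4)
  expect_warning(ep <- epoch_trials(eeg, 500, events, cfg), "dropped")
  expect_equal(n_trials(ep), 0)
})

test_that("epoch values are an exact cut of the continuous signal", {
  cfg <- preproc_config(fs_target_hz = 200, epoch_window_ms = c(-300, 3000))
  events <- data.frame(onset_ms = c(2000, 9000),
                       category = c("spatial", "verbal"))
  eeg <- matrix(seq_len(2 * 4000), 2, byrow = FALSE)
  ep <- epoch_trials(eeg, 200, events, cfg)
  o <- round(2000 * 200 / 1000) + 1 + round(-300 * 200 / 1000)
  expect_equal(ep$data[1, , 1], eeg[, o])
  expect_equal(ep$data[1, , 660], eeg[, o + 659])
})

test_that("amplitude rejection removes exactly the offending trials", {
  d <- array(0, c(6, 3, 40))
  d[4, 2, 10] <- 200
  ep <- epoch_set(d, seq(-300, by = 10, length.out = 40), 100,
                  rep(c("visual", "spatial", "verbal"), 2),
                  data.frame(trial_index = 1:6))
  clean <- reject_artifacts(ep, preproc_config())
  expect_equal(n_trials(clean), 5)
  expect_equal(attr(clean, "rejection")$trial, 4)
  expect_equal(attr(clean, "rejection")$channels, "2")
  expect_equal(clean$trial_meta$trial_index, c(1:3, 5:6))

  none <- reject_artifacts(epoch_set(array(0, c(4, 2, 10)),
                                     seq(-300, by = 10, length.out = 10),
                                     100, rep("visual", 4),
                                     data.frame(trial_index = 1:4)),
                           preproc_config())
  expect_equal(n_trials(none), 4)
  expect_equal(attr(none, "n_rejected"), 0)
})

test_that("epoch/label alignment survives arbitrary rejection patterns", {
  set.seed(77)
  for (rep in 1:5) {
    nt <- 30
    d <- array(rnorm(nt * 2 * 20, sd = 10), c(nt, 2, 20))
    bad <- sample(nt, sample(0:10, 1))
    for (i in bad) d[i, sample(2, 1), sample(20, 1)] <- 400
    labs <- sample(c("visual", "spatial", "verbal"), nt, replace = TRUE)
    ep <- epoch_set(d, seq(-300, by = 10, length.out = 20), 100, labs,
                    data.frame(trial_index = 1:nt, tag = paste0("t", 1:nt)))
    clean <- reject_artifacts(ep, preproc_config())
    keep <- setdiff(1:nt, bad)
    expect_equal(clean$trial_meta$trial_index, keep)
    expect_equal(as.character(clean$labels), labs[keep])
    expect_equal(clean$data[, , ], d[keep, , , drop = FALSE][, , ])
  }
})

test_that("filtering a margin-padded segment matches filtering the whole recording", {
  pc <- preproc_config(fs_target_hz = 500, epoch_window_ms = c(-300, 3000))
  fs <- 500
  n <- 30 * fs
  eeg <- pink_noise(2, n, 1, 10, seed = 91)
  events <- data.frame(onset_ms = 12000, category = "visual")
  full <- bandpass_resample(eeg, fs, pc)
  ep_full <- epoch_trials(full$eeg, 500, events, pc)
  seg_idx <- (5 * fs + 1):(20 * fs)
  seg <- eeg[, seg_idx, drop = FALSE]
  pseg <- bandpass_resample(seg, fs, pc)
  ev2 <- data.frame(onset_ms = 7000, category = "visual")
  ep_seg <- epoch_trials(pseg$eeg, 500, ev2, pc)
  # DC offsets of the two cuts differ; compare after removing each mean
  a <- ep_full$data[1, , ] - rowMeans(ep_full$data[1, , ])
  b <- ep_seg$data[1, , ] - rowMeans(ep_seg$data[1, , ])
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("behaviour scoring counts missing responses as incorrect", {
  tt <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(score_behavior(tt), 0.75)
  expect_equal(score_behavior(data.frame(correct = rep(TRUE, 10))), 1)
  tt$correct[2] <- NA
  expect_equal(score_behavior(tt), 0.5)
  expect_error(score_behavior(data.frame(correct = logical(0))), "empty")
  expect_equal(score_behavior(data.frame(correct = c(rep(TRUE, 96),
                                                     rep(FALSE, 32)))),
               0.75)
})

test_that("exclusion rules are inclusive at chance and strict at 200 trials", {
  mk <- function(id, nt, acc) {
    ep <- epoch_set(array(0, c(nt, 2, 5)),
                    seq(-300, by = 10, length.out = 5), 100,
                    rep("visual", nt), data.frame(trial_index = seq_len(nt)),
                    subject_meta = list(subject_id = id,
                                        behavioral_accuracy_observed = acc))
    ep
  }
  res <- apply_exclusions(list(mk("a", 300, 0.50), mk("b", 200, 0.9),
                               mk("c", 201, 0.9), mk("d", 384, 0.9)),
                          preproc_config())
  rep <- res$report
  expect_true(rep$excluded[rep$subject_id == "a"])   # accuracy 0.50 is out
  expect_true(rep$excluded[rep$subject_id == "b"])   # exactly 200 is out
  expect_false(rep$excluded[rep$subject_id == "c"])  # 201 is in
  expect_false(rep$excluded[rep$subject_id == "d"])
  expect_equal(length(res$retained), 2)
  expect_match(rep$reason[rep$subject_id == "a"], "chance")

  expect_error(apply_exclusions(list(mk("a", 10, 0.4)), preproc_config()),
               "all subjects excluded")
})

test_that("incorrect-response trials are retained for decoding", {
  cfg <- quick_cfg(n = 10, ch = 4, fs = 100)
  ep <- synthesize_epochs(cfg, null_model(),
                          subject_spec("s", behavioral_accuracy = 0.6),
                          seed = 3)
  expect_true(any(!ep$trial_meta$correct))
  expect_equal(n_trials(ep), 30)
})
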