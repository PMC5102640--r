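test_that("extract_trials cuts 22-sample windows per event", {
  rec <- make_clean_recording(n_high = 6)
  hemo <- preprocess_recording(rec, filter = FALSE, detrend = FALSE)
  ts <- extract_trials(hemo)
  expect_equal(dim(ts$hbo)[1], 22)        # 11 s at 2 Hz
  expect_equal(dim(ts$hbo)[2], 6)
  expect_equal(dim(ts$hbo)[3], 16)
  expect_error(extract_trials(hemo, condition = "Font"), "no events")
})

test_that("a 66-trial High-Complexity design yields 66 trials per channel", {
  sched <- generate_schedule(0, 0, 66, seed = 12)
  truth <- ground_truth("healthy", 30, matrix(0.5, 16, 3))
  rec <- simulate_subject(sched, truth, zero_noise_params())
  hemo <- preprocess_recording(rec, filter = FALSE, detrend = FALSE)
  ts <- extract_trials(hemo)
  expect_equal(dim(ts$hbo)[2], 66)
})

test_that("trials truncated by the recording end are skipped with warning", {
  rec <- make_clean_recording(n_high = 2)
  hemo <- preprocess_recording(rec, filter = FALSE, detrend = FALSE)
  # forge an event 1 s before the end
  hemo$schedule$events <- rbind(
    hemo$schedule$events,
    data.frame(onset_s = hemo$schedule$total_duration_s - 1,
               duration_s = 5, condition = "HighComplexity"))
  expect_warning(ts <- extract_trials(hemo), "truncated")
  expect_equal(dim(ts$hbo)[2], 2)
})

test_that("trial_passes implements the three screening criteria", {
  t <- seq(0, 10.5, by = 0.5)
  bump <- 0.5 + 0.5 * sin(2 * pi * t / 11)
  # perfectly anticorrelated, positive-mean trial: retained
  v <- trial_passes(bump, -bump)
  expect_true(v$anticorrelation && v$oxy_dominance && v$positivity)
  expect_true(v$retained)
  # positively correlated: rejected on anticorrelation
  v2 <- trial_passes(bump, bump - 1.5)
  expect_false(v2$anticorrelation)
  expect_false(v2$retained)
  # negative mean HbO with good anticorrelation: rejected on positivity
  neg <- bump - 0.9                      # mean about -0.2
  v3 <- trial_passes(neg, -0.5 * neg - 0.3)
  expect_true(v3$anticorrelation)
  expect_false(v3$positivity)
  expect_false(v3$retained)
  # zero-variance window: degenerate rejection, not an error
  v4 <- trial_passes(rep(1, 22), -bump)
  expect_false(v4$retained)
  expect_identical(v4$reason, "degenerate")
  # all_samples positivity mode is stricter
  dip <- bump
  dip[3] <- -0.01
  expect_true(trial_passes(dip, -dip)$retained)
  expect_false(trial_passes(dip, -dip,
                            positivity_mode = "all_samples")$retained)
})

test_that("verdicts are independent of trial order", {
  rec <- make_clean_recording(n_high = 5)
  hemo <- preprocess_recording(rec)
  ts <- apply_trial_qc(extract_trials(hemo))
  perm <- c(3, 1, 5, 2, 4)
  ts_p <- extract_trials(hemo)
  ts_p$hbo <- ts_p$hbo[, perm, , drop = FALSE]
  ts_p$hbr <- ts_p$hbr[, perm, , drop = FALSE]
  ts_p$event_index <- ts_p$event_index[perm]
  ts_p <- apply_trial_qc(ts_p)
  q1 <- ts$qc[ts$qc$channel == 1, ]
  q2 <- ts_p$qc[ts_p$qc$channel == 1, ]
  expect_equal(q2$retained, q1$retained[perm])
  expect_equal(q2$r, q1$r[perm])
})

test_that("clean trials are fully retained; sign-flipped coupling kills all", {
  rec <- make_clean_recording(amplitude = 0.8)
  hemo <- preprocess_recording(rec, filter = FALSE, detrend = FALSE)
  ts <- apply_trial_qc(extract_trials(hemo))
  expect_true(all(ts$qc$retained))
  # flip the HbR coupling sign: anticorrelation screen must reject all
  flipped <- make_clean_recording(amplitude = 0.8)
  np <- zero_noise_params()
  np$hbr_ratio <- -np$hbr_ratio
  sched <- generate_schedule(0, 0, 6, seed = 11, total_duration_s = 200)
  truth <- ground_truth("healthy", 30, matrix(0.8, 16, 3))
  rec2 <- simulate_subject(sched, truth, np)
  hemo2 <- preprocess_recording(rec2, filter = FALSE, detrend = FALSE)
  ts2 <- apply_trial_qc(extract_trials(hemo2))
  expect_false(any(ts2$qc$retained))
})

test_that("channel and subject pruning fire exactly at the boundaries", {
  make_ts <- function(n_rej, n_tot = 10, nch = 16) {
    # hand-built trial set: trial k rejected iff k <= n_rej
    wlen <- 22
    hbo <- array(0, c(wlen, n_tot, nch))
    hbr <- array(0, c(wlen, n_tot, nch))
    t <- seq_len(wlen)
    good <- 0.5 + 0.4 * sin(2 * pi * t / wlen)
    for (k in seq_len(n_tot)) {
      for (ch in seq_len(nch)) {
        if (k <= n_rej) {
          hbo[, k, ch] <- good
          hbr[, k, ch] <- good        # positively correlated -> rejected
        } else {
          hbo[, k, ch] <- good
          hbr[, k, ch] <- -good
        }
      }
    }
    structure(list(subject = "X", group = "healthy", fs = 2,
                   condition = "HighComplexity", window_s = 11,
                   event_index = seq_len(n_tot), hbo = hbo, hbr = hbr,
                   qc = NULL), class = "trial_set")
  }
  # 8 of 10 rejected (fraction 0.80): channel dropped (inclusive boundary)
  pr8 <- prune_channels_subjects(list(apply_trial_qc(make_ts(8))))
  expect_false(any(pr8$channel_retained))
  expect_false(pr8$subject_retained)
  # 7 of 10 rejected: kept
  pr7 <- prune_channels_subjects(list(apply_trial_qc(make_ts(7))))
  expect_true(all(pr7$channel_retained))
  expect_true(pr7$subject_retained)
  # full rejection mirrors into the report
  pr10 <- prune_channels_subjects(list(apply_trial_qc(make_ts(10))))
  expect_false(pr10$subject_retained)
  expect_equal(sum(pr10$report$retained_counts), 0)
})

test_that("block_average averages retained trials only", {
  wlen <- 22
  hbo <- array(0, c(wlen, 8, 16))
  hbr <- array(0, c(wlen, 8, 16))
  t <- seq_len(wlen)
  base <- 0.5 + 0.4 * sin(2 * pi * t / wlen)
  set.seed(30)
  for (k in 1:8) {
    for (ch in 1:16) {
      x <- base + rnorm(wlen, 0, 0.05)
      hbo[, k, ch] <- x
      hbr[, k, ch] <- if (k <= 5) -x else x   # 3 rejected trials
    }
  }
  ts <- apply_trial_qc(structure(
    list(subject = "X", group = "healthy", fs = 2,
         condition = "HighComplexity", window_s = 11,
         event_index = 1:8, hbo = hbo, hbr = hbr, qc = NULL),
    class = "trial_set"))
  avg <- block_average(ts, 4)
  expect_equal(avg$n_trials, 5)
  expect_equal(avg$HbO, rowMeans(hbo[, 1:5, 4]))   # scratch mean oracle
  # mean of two near-constant levels, and the mean of identical trials
  wig <- 0.01 * sin(2 * pi * t / wlen)
  hbo2 <- hbo[, 1:2, , drop = FALSE]
  hbo2[, 1, 1] <- 1 + wig
  hbo2[, 2, 1] <- 3 + wig
  hbo2[, 2, 2] <- hbo2[, 1, 2]           # channel 2: identical trials
  hbr2 <- -hbo2
  ts2 <- apply_trial_qc(structure(
    list(subject = "X", group = "healthy", fs = 2,
         condition = "HighComplexity", window_s = 11,
         event_index = 1:2, hbo = hbo2, hbr = hbr2, qc = NULL),
    class = "trial_set"))
  expect_equal(block_average(ts2, 1)$HbO, 2 + wig)
  expect_equal(block_average(ts2, 2)$HbO, hbo2[, 1, 2])
  # adding a rejected trial never changes the average
  ts3 <- apply_trial_qc(structure(
    list(subject = "X", group = "healthy", fs = 2,
         condition = "HighComplexity", window_s = 11,
         event_index = 1:8, hbo = hbo, hbr = hbr, qc = NULL),
    class = "trial_set"))
  ts_no6 <- apply_trial_qc(structure(
    list(subject = "X", group = "healthy", fs = 2,
         condition = "HighComplexity", window_s = 11,
         event_index = 1:5, hbo = hbo[, 1:5, , drop = FALSE],
         hbr = hbr[, 1:5, , drop = FALSE], qc = NULL),
    class = "trial_set"))
  expect_equal(block_average(ts3, 2)$HbO, block_average(ts_no6, 2)$HbO)
  # a channel with every trial rejected cannot be averaged
  ts_bad <- apply_trial_qc(structure(
    list(subject = "X", group = "healthy", fs = 2,
         condition = "HighComplexity", window_s = 11,
         event_index = 1:2, hbo = hbo2, hbr = hbo2, qc = NULL),
    class = "trial_set"))
  expect_error(block_average(ts_bad, 1), "no retained")
})
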