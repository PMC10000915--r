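test_that("morphology matches hand computation on short vectors", {
  # flags:            F F T T T F F T F F
  x <- c(0, 0, 5, 5, 5, 0, 0, 5, 0, 0)
  flags <- abs(x) > 1
  # erosion, centred window of 3: only the middle of the 3-run survives
  expect_equal(erode1d(flags, 3),
               c(F, F, F, T, F, F, F, F, F, F))
  # dilation of that by 3 restores the block, the isolated spike stays gone
  expect_equal(dilate1d(erode1d(flags, 3), 3),
               c(F, F, T, T, T, F, F, F, F, F))
  # all-zero trace gives an empty mask
  m0 <- detect_artifact_blocks(rep(0, 100), 1000, amp_threshold = 1,
                               erosion_len = 3, dilation_len = 3)
  expect_equal(nrow(m0$intervals), 0)
  expect_false(any(m0$flags))
  # a single 1-sample excursion is eroded away
  x1 <- rep(0, 100); x1[50] <- 10
  m1 <- detect_artifact_blocks(x1, 1000, amp_threshold = 1,
                               erosion_len = 3, dilation_len = 3)
  expect_equal(nrow(m1$intervals), 0)
  expect_error(detect_artifact_blocks(x1, 1000, amp_threshold = 0,
                                      erosion_len = 3, dilation_len = 3),
               "amp_threshold")
})

test_that("synthetic gradient blocks are recovered at the right count and edges", {
  et <- two_unit_truth(seed = 31)
  rec <- gen_raw_ephys(et, 10)
  mask <- detect_artifact_blocks(rec$trace, rec$fs_hz, amp_threshold = 1e-4,
                                 erosion_len = 32, dilation_len = 64)
  truth <- rec$artifact_intervals
  expect_equal(nrow(mask$intervals), nrow(truth))
  pad <- (32 + 64) / rec$fs_hz   # morphology can widen edges by the pad
  expect_true(all(abs(mask$intervals$start_s - truth$start_s) <= pad))
  expect_true(all(abs(mask$intervals$end_s - truth$end_s) <= pad))
  # every flagged interval actually covers its block
  expect_true(all(mask$intervals$start_s <= truth$start_s + 1e-9))
  expect_true(all(mask$intervals$end_s >= truth$end_s - 1e-9))
})

test_that("artifact mask is monotone in the threshold", {
  et <- two_unit_truth(seed = 13)
  rec <- gen_raw_ephys(et, 4)
  lo <- detect_artifact_blocks(rec$trace, rec$fs_hz, amp_threshold = 0.5e-4,
                               erosion_len = 16, dilation_len = 32)
  hi <- detect_artifact_blocks(rec$trace, rec$fs_hz, amp_threshold = 2e-4,
                               erosion_len = 16, dilation_len = 32)
  expect_true(all(lo$flags[hi$flags]))   # higher threshold => subset
})

test_that("excision preserves length bookkeeping and the original clock", {
  x <- stats::rnorm(1000)
  none <- excise_blocks(x, rep(FALSE, 1000), fs_hz = 1000)
  expect_identical(none$trace, x)
  flags <- rep(FALSE, 1000); flags[101:200] <- TRUE
  cut <- excise_blocks(x, flags, fs_hz = 1000)
  expect_length(cut$trace, 900)
  expect_true(all(diff(cut$time_s) > 0))
  # re-inserting zeros at flagged positions reconstructs the original length
  rebuilt <- numeric(1000)
  rebuilt[!flags] <- cut$trace
  expect_length(rebuilt, length(x))
  expect_identical(rebuilt[!flags], x[!flags])
  expect_error(excise_blocks(x, flags[1:10], fs_hz = 1000), "length")
})

test_that("spike detection: perfect on noiseless trains, quantified on noise", {
  # noiseless template train: 100% recall, 0 false positives
  et0 <- ephys_truth(data.frame(duration_ms = 0.5, amplitude = 100e-6,
                                rate = 8, stim_mult = 1, drug_mult = 1),
                     noise_sd = 0, artifact_amplitude = 0, seed = 3)
  rec0 <- gen_raw_ephys(et0, 5, artifacts = FALSE)
  ev0 <- detect_spikes(rec0$trace, fs_hz = rec0$fs_hz)
  expect_equal(length(ev0$time_s), nrow(rec0$true_spikes))
  expect_true(all(vapply(rec0$true_spikes$time_s, function(t)
    min(abs(ev0$time_s - t)) < 5e-4, logical(1))))
  # flat trace: zero events, no failure
  expect_length(detect_spikes(rep(0, 64000), fs_hz = 32000)$time_s, 0)

  # pure-noise false-positive rate vs a brute-force Monte-Carlo oracle
  fs <- 32000; dur <- 2; n <- fs * dur
  brute_count <- function(x, thr, lock) {
    cnt <- 0L; i <- 1L
    while (i <= n) {
      if (abs(x[i]) > thr) { cnt <- cnt + 1L; i <- i + lock } else i <- i + 1L
    }
    cnt
  }
  set.seed(40)
  null_counts <- replicate(20, brute_count(stats::rnorm(n), 3, 32))
  bound <- max(null_counts) * 1.5
  ev <- detect_spikes(stats::rnorm(n), k = 3, fs_hz = fs)
  expect_lt(length(ev$time_s), bound)

  # SNR 8 mixed train: recall at least 0.95 against generator truth
  et8 <- ephys_truth(data.frame(duration_ms = c(0.4, 0.8),
                                amplitude = c(80e-6, 80e-6),
                                rate = c(5, 5), stim_mult = 1, drug_mult = 1),
                     noise_sd = 10e-6, artifact_amplitude = 0, seed = 77)
  rec8 <- gen_raw_ephys(et8, 20, artifacts = FALSE)
  ev8 <- detect_spikes(rec8$trace, fs_hz = rec8$fs_hz)
  recall <- mean(vapply(rec8$true_spikes$time_s, function(t)
    min(abs(ev8$time_s - t)) < 5e-4, logical(1)))
  expect_gte(recall, 0.95)
})

test_that("unit sorting separates distinct templates and applies ISI QC", {
  et <- two_unit_truth(seed = 21)
  rec <- gen_raw_ephys(et, 30)
  mask <- detect_artifact_blocks(rec$trace, rec$fs_hz, amp_threshold = 1e-4,
                                 erosion_len = 32, dilation_len = 64)
  ev <- detect_spikes(excise_blocks(rec$trace, mask))
  srt <- assign_units(ev)
  expect_equal(srt$k, 2)
  # match each true spike outside artifact blocks to the nearest kept event
  kept_t <- unlist(srt$trains)
  kept_u <- rep(seq_along(srt$trains),
                vapply(srt$trains, length, integer(1)))
  art <- rec$artifact_intervals
  outside <- vapply(rec$true_spikes$time_s, function(t)
    !any(t >= art$start_s - 0.003 & t <= art$end_s + 0.003), logical(1))
  truth <- rec$true_spikes[outside, ]
  det <- vapply(truth$time_s, function(t) {
    i <- which.min(abs(kept_t - t))
    if (abs(kept_t[i] - t) < 5e-4) kept_u[i] else NA_integer_
  }, integer(1))
  conf <- table(truth$unit_id, det)
  # map true units to their majority cluster; accuracy over matched spikes
  acc <- sum(apply(conf, 1, max)) / sum(conf)
  expect_gte(acc, 0.95)
  expect_gte(mean(!is.na(det)), 0.95)
  # all sorted trains respect the 1 ms ISI floor
  for (tr in srt$trains) if (length(tr) > 1) expect_gte(min(diff(tr)), 0.001)

  # one template only: a single cluster
  et1 <- ephys_truth(data.frame(duration_ms = 0.5, amplitude = 100e-6,
                                rate = 10, stim_mult = 1, drug_mult = 1),
                     noise_sd = 5e-6, artifact_amplitude = 0, seed = 9)
  rec1 <- gen_raw_ephys(et1, 10, artifacts = FALSE)
  srt1 <- assign_units(detect_spikes(rec1$trace, fs_hz = rec1$fs_hz))
  expect_equal(srt1$k, 1)
})

test_that("ISI QC drops same-unit events closer than 1 ms", {
  # hand-built events 0.5 ms apart: the later one must be removed
  fs <- 32000
  tmpl <- spike_template(0.5, 100e-6, fs)
  x <- numeric(fs)
  for (t0 in c(0.100, 0.1005, 0.300)) {
    a <- round(t0 * fs)
    x[a:(a + length(tmpl$w) - 1)] <- x[a:(a + length(tmpl$w) - 1)] + tmpl$w
  }
  ev <- detect_spikes(x, fs_hz = fs, lockout_s = 0.0004)
  srt <- assign_units(ev, isi_min_s = 0.001)
  tt <- sort(unlist(srt$trains))
  expect_gte(min(diff(tt)), 0.001)
})

test_that("cell-type classification partitions the feature plane", {
  expect_equal(classify_unit(0.33, 6), "interneuron")
  expect_equal(classify_unit(0.8, 1), "putative_efferent")
  expect_equal(classify_unit(0.55, 3), "unclassified")
  expect_equal(classify_unit(0.4, 1), "unclassified")  # brief but slow
  # exhaustive and exclusive over a grid of the plane
  grid <- expand.grid(dur = seq(0.1, 1.2, by = 0.05),
                      rate = seq(0, 10, by = 0.5))
  cls <- mapply(classify_unit, grid$dur, grid$rate)
  expect_true(all(cls %in% c("interneuron", "putative_efferent",
                             "unclassified")))
  expect_equal(sum(is.na(cls)), 0)
})
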