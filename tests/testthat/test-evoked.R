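test_that("peri-event histograms are flat for homogeneous trains and track rate steps", {
  p <- full_paradigm()
  onsets <- stim_onsets_s(p)
  dur <- p$n_trials * trial_duration_s(p)
  set.seed(61)
  # homogeneous Poisson: flat within sampling error
  ph <- build_peh(poisson_train(5, dur), onsets)
  expect_equal(length(ph$rate), 60)   # default window [-10, 50), 1 s bins
  expect_lt(abs(mean(ph$rate) - 5), 3 * sqrt(5 / (10 * 60)) * 3)
  expect_lt(stats::sd(ph$rate), 3 * sqrt(5 / 10) )
  # rate doubling during stimulation: stim bins near 200% of baseline
  ep <- data.frame(start_s = onsets, end_s = onsets + 40, mult = 2)
  ph2 <- build_peh(gen_spike_times(dur, 5, epochs = ep), onsets)
  base <- mean(ph2$rate[1:10])
  stim <- mean(ph2$rate[11:50])
  expect_lt(abs(stim / base - 2), 0.25)
  expect_lt(abs(mean(ph2$norm_rate[11:50]) - 200), 25)
  # empty train: all-zero histogram, no failure
  ph0 <- build_peh(numeric(0), onsets)
  expect_true(all(ph0$rate == 0))
  expect_error(build_peh(1:10, numeric(0)), "onset")
})

test_that("the 150 ms trigger delay shifts event alignment as metadata says", {
  p <- full_paradigm(n_trials = 30)
  dur <- p$n_trials * trial_duration_s(p)
  on_delay <- stim_onsets_s(p)                        # with 150 ms delay
  on_trig <- stim_onsets_s(p, include_delay = FALSE)  # MR trigger clock
  # events locked tightly to the true (delayed) onsets
  times <- as.vector(vapply(on_delay, function(o) o + seq(0.02, 0.92, 0.1),
                            numeric(10)))
  ph_ok <- build_peh(times, on_delay, window = c(-2, 3), bin_width = 0.05)
  ph_off <- build_peh(times, on_trig, window = c(-2, 3), bin_width = 0.05)
  ctr <- (ph_ok$edges[-1] + ph_ok$edges[-length(ph_ok$edges)]) / 2
  first_ok <- min(ctr[ph_ok$rate > 0])
  first_off <- min(ctr[ph_off$rate > 0])
  expect_equal(first_off - first_ok, 0.15, tolerance = 1e-9)
})

test_that("normalization is idempotent and pooling commutes with averaging", {
  p <- full_paradigm()
  onsets <- stim_onsets_s(p)
  dur <- p$n_trials * trial_duration_s(p)
  set.seed(71)
  pehs <- replicate(4, build_peh(poisson_train(4, dur), onsets),
                    simplify = FALSE)
  ph <- pehs[[1]]
  base_bins <- which(ph$edges[-1] <= 0)
  renorm <- 100 * ph$norm_rate / mean(ph$norm_rate[base_bins])
  expect_equal(renorm, ph$norm_rate, tolerance = 1e-12)
  expect_equal(mean(ph$norm_rate[base_bins]), 100, tolerance = 1e-12)
  # population histogram equals the bin-wise mean of unit histograms
  pop <- population_peh(pehs)
  manual <- rowMeans(vapply(pehs, function(q) q$rate,
                            numeric(length(ph$rate))))
  expect_equal(pop$rate, manual, tolerance = 1e-12)
})

test_that("response polarity classification follows the 2-SD rule", {
  p <- full_paradigm()
  onsets <- stim_onsets_s(p)
  dur <- p$n_trials * trial_duration_s(p)
  set.seed(81)
  mk <- function(mult) {
    ep <- data.frame(start_s = onsets, end_s = onsets + 40, mult = mult)
    build_peh(gen_spike_times(dur, 5, epochs = ep), onsets)
  }
  expect_equal(classify_response(mk(3))$polarity, "excitatory")
  expect_equal(classify_response(mk(1))$polarity, "none")
  expect_equal(classify_response(mk(0.1))$polarity, "inhibitory")
  expect_true(is.na(classify_response(mk(1))$magnitude_pct_of_baseline))
  # zero-variance zero-rate baseline stays "none"
  ph0 <- build_peh(numeric(0), onsets)
  expect_equal(classify_response(ph0)$polarity, "none")
  # polarity is invariant to uniform rescaling of the whole train's rate
  set.seed(82)
  ep <- data.frame(start_s = onsets, end_s = onsets + 40, mult = 3)
  lo <- build_peh(gen_spike_times(dur, 2, epochs = ep), onsets)
  hi <- build_peh(gen_spike_times(dur, 12, epochs = ep), onsets)
  expect_equal(classify_response(lo)$polarity,
               classify_response(hi)$polarity)
})

test_that("magnitude comparison recovers exact ratios and labels transitions", {
  mk_summary <- function(id, polarity, mag) {
    structure(list(unit_id = id, polarity = polarity,
                   magnitude_pct_of_baseline = mag,
                   baseline_mean = 5, baseline_sd = 0.5, stim_mean = 10),
              class = "response_summary")
  }
  pre <- lapply(1:6, function(i) mk_summary(i, "excitatory", 100 + 20 * i))
  # identical pre/post: zero change, p = 1
  same <- compare_magnitudes(pre, pre)
  expect_equal(same$mean_change_pct, 0)
  expect_equal(same$p_value, 1)
  # exact 1.76x scaling: mean change exactly 76%
  post <- lapply(pre, function(s) {
    s$magnitude_pct_of_baseline <- s$magnitude_pct_of_baseline * 1.76
    s
  })
  res <- compare_magnitudes(pre, post)
  expect_equal(res$mean_change_pct, 76, tolerance = 1e-10)
  expect_lt(res$p_value, 0.05)
  # pre-none post-excitatory units become newly_acquired, excluded from mean
  pre2 <- pre
  pre2[[1]]$polarity <- "none"
  pre2[[1]]$magnitude_pct_of_baseline <- NA_real_
  res2 <- compare_magnitudes(pre2, post)
  expect_equal(res2$n_pairs, 5)
  expect_equal(res2$transitions$status[res2$transitions$unit_id == 1],
               "newly_acquired")
  expect_equal(res2$mean_change_pct, 76, tolerance = 1e-10)
  # abolished label for excitatory-pre, none-post
  post2 <- post
  post2[[2]]$polarity <- "none"
  res3 <- compare_magnitudes(pre, post2)
  expect_equal(res3$transitions$status[res3$transitions$unit_id == 2],
               "abolished")
  expect_error(compare_magnitudes(pre[1], post[1]), "pairs")
})
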