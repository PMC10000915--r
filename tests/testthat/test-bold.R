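test_that("motion QC excludes shifted trials and averaging reduces noise", {
  p <- small_paradigm(n_trials = 4)
  mask <- rect_mask(c(16, 16, 1), 7:9, 7:9)
  bt <- gen_bold_trials(p, bold_truth(mask, 1.5, noise_sd_pct = 0.4,
                                      seed = 5), grid = c(16, 16, 1))
  # identical trials: average equals any input (post-discard images)
  same <- list(bt$trials[[1]], bt$trials[[1]])
  av_same <- qc_and_average(same, paradigm = p)
  expect_equal(av_same$mean_trial,
               bt$trials[[1]][, , , -(1:p$n_discard), drop = FALSE])
  # structured volumes (a bright blob on background): mid-trial 2-voxel shift
  n_img <- n_images_per_trial(p)
  blob <- function() {
    v <- array(100, c(16, 16, 1, n_img))
    v[6:9, 6:9, 1, ] <- 5000
    v
  }
  trials <- replicate(4, blob(), simplify = FALSE)
  sh <- blob()
  for (i in (n_img %/% 2):n_img) {
    img <- array(100, c(16, 16, 1))
    img[8:11, 6:9, 1] <- 5000                     # blob moved +2 in x
    sh[, , , i] <- img
  }
  trials[[2]] <- sh
  expect_gt(motion_metric(sh), 1)
  expect_equal(motion_metric(trials[[1]]), 0)
  av <- suppressMessages(qc_and_average(trials, paradigm = p,
                                        motion_limit = 1))
  expect_equal(av$excluded, 2L)
  expect_equal(av$n_used, 3L)
  expect_error(suppressMessages(
    qc_and_average(list(sh), paradigm = p, motion_limit = 0.5)), "excluded")
  # averaging n noiseless-signal trials shrinks noise SD by sqrt(n)
  p10 <- small_paradigm(n_trials = 10)
  flat <- gen_bold_trials(p10, bold_truth(rect_mask(c(16, 16, 1), 7:9, 7:9),
                                          0, noise_sd_pct = 1, seed = 8),
                          grid = c(16, 16, 1))
  av10 <- qc_and_average(flat)
  sd1 <- stats::sd(flat$trials[[1]] - 1000)
  sd10 <- stats::sd(av10$mean_trial - 1000)
  expect_equal(sd10, sd1 / sqrt(10), tolerance = 0.05)
})

test_that("percent change is exact on step responses", {
  p <- stim_paradigm()
  n <- n_images_per_trial(p) - p$n_discard
  # constant voxel: all zeros
  expect_equal(pct_change(rep(500, n), p), rep(0, n))
  # steps reproduce the printed effect sizes exactly
  for (amp in c(1.88, -1.97)) {
    x <- rep(1000, n)
    x[stim_image_idx(p)] <- 1000 * (1 + amp / 100)
    pc <- pct_change(x, p)
    expect_equal(mean(pc[stim_image_idx(p)]), amp, tolerance = 1e-12)
    expect_equal(mean(pc[baseline_image_idx(p)]), 0, tolerance = 1e-12)
  }
  # non-positive baseline: voxel excluded
  expect_null(pct_change(rep(0, n), p))
})

test_that("SVM mapping finds small regions of either sign and is quiet under the null", {
  p <- full_paradigm()
  # 3x3 region at high contrast-to-noise: Dice overlap >= 0.8
  mask <- rect_mask(c(20, 20, 1), 9:11, 9:11)
  bt <- gen_bold_trials(p, bold_truth(mask, 3, noise_sd_pct = 0.3, seed = 2),
                        grid = c(20, 20, 1))
  out <- bold_pipeline(bt)
  inter <- sum(out$map$labels & mask)
  dice <- 2 * inter / (out$map$n_active + sum(mask))
  expect_gte(dice, 0.8)
  # region-mean correlations are strongly positive inside the truth
  expect_gt(mean(out$map$correlation[mask]), 0.8)

  # negative-amplitude region: detected with negative correlations
  btn <- gen_bold_trials(p, bold_truth(mask, -3, noise_sd_pct = 0.3,
                                       seed = 2), grid = c(20, 20, 1))
  outn <- bold_pipeline(btn)
  intern <- sum(outn$map$labels & mask)
  expect_gte(2 * intern / (outn$map$n_active + sum(mask)), 0.8)
  expect_lt(mean(outn$map$correlation[mask]), -0.8)
  expect_lt(outn$metrics$magnitude_pct, 0)

  # pure noise: active fraction stays at or below the rejection rate
  null <- gen_bold_trials(p, bold_truth(array(FALSE, c(20, 20, 1)), 0,
                                        noise_sd_pct = 0.3, seed = 3),
                          grid = c(20, 20, 1))
  avn <- qc_and_average(null)
  mapn <- svm_activation_map(avn, nu = 0.05)
  expect_lte(mapn$n_active / 400, 0.05)
})

test_that("area arithmetic is exact for the acquisition voxel size", {
  p <- full_paradigm()
  mask <- rect_mask(c(20, 20, 1), 9:11, 9:11)
  bt <- gen_bold_trials(p, bold_truth(mask, 3, noise_sd_pct = 0.2, seed = 6),
                        grid = c(20, 20, 1))
  out <- bold_pipeline(bt)
  expect_equal(out$map$area_mm2, out$map$n_active * 0.375 * 0.375)
  expect_equal(out$map$volume_mm3, out$map$n_active * 0.375 * 0.375 * 1.0)
})

test_that("FWHM matches closed-form geometry and a brute-force scan", {
  # ideal 40 s boxcar sampled at TR 2: duration 40 s
  p <- stim_paradigm()
  tt <- image_times_s(p)
  box <- rep(0, length(tt))
  box[stim_image_idx(p)] <- 2
  expect_equal(fwhm(tt, box)$fwhm_s, 40)
  # triangle peaking at 2%, base 40 s: FWHM is half the base
  tt2 <- seq(0, 60, by = 0.5)
  tri <- pmax(0, 2 * (1 - abs(tt2 - 30) / 20))
  expect_equal(fwhm(tt2, tri)$fwhm_s, 20)
  # negative responses measure the same width as their mirror image
  expect_equal(fwhm(tt2, -tri)$fwhm_s, 20)
  # brute-force half-maximum crossing scan agrees on random unimodal curves
  set.seed(91)
  for (i in 1:10) {
    pk <- runif(1, 20, 40); wl <- runif(1, 5, 15); wr <- runif(1, 5, 15)
    y <- exp(-(pmax(0, pk - tt2) / wl)^2) * exp(-(pmax(0, tt2 - pk) / wr)^2)
    ref <- fwhm(tt2, y)
    half <- max(y) / 2
    above <- which(y >= half)
    lo <- min(above); hi <- max(above)
    interp <- function(i1, i2) {
      tt2[i1] + (half - y[i1]) / (y[i2] - y[i1]) * (tt2[i2] - tt2[i1])
    }
    brute <- interp(hi, min(hi + 1, length(y))) - interp(lo, max(lo - 1, 1))
    expect_equal(ref$fwhm_s, brute, tolerance = 1e-9)
  }
})

test_that("the full BOLD pipeline is sign-equivariant", {
  p <- full_paradigm()
  mask <- rect_mask(c(20, 20, 1), 9:12, 9:12)
  bt <- gen_bold_trials(p, bold_truth(mask, 2.5, noise_sd_pct = 0.3,
                                      seed = 12), grid = c(20, 20, 1))
  neg <- bt
  # reflect every voxel about its own trial baseline mean (the mean over the
  # post-discard baseline images), which negates the % change series exactly
  bidx <- seq.int(p$n_discard + 1L, p$n_baseline)
  neg$trials <- lapply(bt$trials, function(v) {
    b <- apply(v[, , , bidx, drop = FALSE], 1:3, mean)
    sweep(-v, 1:3, 2 * b, "+")
  })
  out_pos <- bold_pipeline(bt, seed = 4)
  out_neg <- bold_pipeline(neg, seed = 4)
  expect_equal(out_neg$map$labels, out_pos$map$labels)
  expect_equal(out_neg$map$area_mm2, out_pos$map$area_mm2)
  expect_equal(out_neg$metrics$magnitude_pct, -out_pos$metrics$magnitude_pct,
               tolerance = 1e-8)
  expect_equal(out_neg$metrics$duration_s, out_pos$metrics$duration_s,
               tolerance = 1e-8)
  expect_equal(out_neg$map$correlation, -out_pos$map$correlation,
               tolerance = 1e-8)
})

test_that("metrics recover generator amplitude within noise error", {
  p <- full_paradigm()
  mask <- rect_mask(c(20, 20, 1), 9:11, 9:11)
  mags <- vapply(1:5, function(s) {
    bt <- gen_bold_trials(p, bold_truth(mask, -1.97, noise_sd_pct = 0.3,
                                        seed = 600 + s),
                          grid = c(20, 20, 1))
    bold_pipeline(bt)$metrics$magnitude_pct
  }, numeric(1))
  sem <- stats::sd(mags) / sqrt(length(mags))
  expect_lt(abs(mean(mags) - (-1.97)), max(2 * sem, 0.1))
})
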