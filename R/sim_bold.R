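#' Single-gamma hemodynamic impulse response
#'
#' A gamma-variate kernel used to shape the BOLD response: the stimulus boxcar
#' is convolved with this kernel so that onsets ramp over several seconds the
#' way measured cortical BOLD time courses do, instead of stepping
#' instantaneously.
#'
#' @param t Times (s) at which to evaluate the kernel, `t >= 0`.
#' @param peak_s Time to peak (s). Default 4.
#' @param shape Gamma shape parameter. Default 6.
#' @return Kernel values at `t`, scaled to unit sum when used discretely.
#' @export
gamma_hrf <- function(t, peak_s = 4, shape = 6) {
  stopifnot(peak_s > 0, shape > 1)
  scale <- peak_s / (shape - 1)
  h <- stats::dgamma(t, shape = shape, scale = scale)
  h
}

#' Stimulus reference regressor for one trial
#'
#' The stimulation boxcar convolved with [gamma_hrf()] and normalised so that
#' its mean over the stimulation images equals exactly 1. With that
#' normalisation an active voxel whose amplitude parameter is `a`% has a
#' stimulation-period mean of exactly `baseline * (1 + a/100)`, so the percent
#' signal change over stimulation images is an unbiased estimate of `a`.
#'
#' @param paradigm A [stim_paradigm()].
#' @param discarded Return the regressor on the post-discard image grid?
#'   Default `TRUE`.
#' @param peak_s,shape Passed to [gamma_hrf()].
#' @return Numeric vector, one value per image of one trial.
#' @export
bold_regressor <- function(paradigm, discarded = TRUE, peak_s = 4, shape = 6) {
  n <- n_images_per_trial(paradigm)
  box <- numeric(n)
  box[stim_image_idx(paradigm, discarded = FALSE)] <- 1
  tk <- (seq_len(n) - 1) * paradigm$tr_s
  h <- gamma_hrf(tk, peak_s = peak_s, shape = shape)
  h <- h / sum(h)
  # direct causal convolution (no FFT ringing): r_i = sum_k box_k h_{i-k+1}
  r <- vapply(seq_len(n), function(i)
    sum(box[seq_len(i)] * h[i - seq_len(i) + 1]), numeric(1))
  r <- r / mean(r[stim_image_idx(paradigm, discarded = FALSE)])
  if (discarded) r <- r[-seq_len(paradigm$n_discard)]
  r
}

#' Ground truth for synthetic BOLD trials
#'
#' @param active_mask Logical array (the volume grid) marking the activated
#'   region; must be a single contiguous region (face-connected).
#' @param amplitude_pct True percent signal change during stimulation, signed;
#'   negative values generate inverted (negative BOLD) responses.
#' @param noise_sd_pct Gaussian noise SD as percent of baseline. Default 0.3.
#' @param drift_pct_per_min Linear drift in percent of baseline per minute.
#'   Default 0.
#' @param baseline Baseline image intensity (arbitrary scanner units).
#'   Default 1000.
#' @param seed RNG seed (required).
#' @return An object of class `bold_truth`.
#' @export
bold_truth <- function(active_mask, amplitude_pct, noise_sd_pct = 0.3,
                       drift_pct_per_min = 0, baseline = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (!is.logical(active_mask)) stop("active_mask must be logical")
  if (is.null(dim(active_mask))) stop("active_mask must be an array")
  if (any(active_mask) && !mask_is_contiguous(active_mask))
    stop("active_mask must be a single contiguous region")
  if (baseline <= 0) stop("baseline must be positive")
  if (noise_sd_pct < 0) stop("noise_sd_pct must be >= 0")
  structure(list(active_mask = active_mask, amplitude_pct = amplitude_pct,
                 noise_sd_pct = noise_sd_pct,
                 drift_pct_per_min = drift_pct_per_min,
                 baseline = baseline, seed = as.integer(seed)),
            class = "bold_truth")
}

# Face-connectivity check via flood fill from the first active voxel.
mask_is_contiguous <- function(mask) {
  dm <- dim(mask)
  if (length(dm) == 2) dm <- c(dm, 1L)
  m <- array(mask, dm)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  seen <- array(FALSE, dm)
  queue <- idx[1, , drop = FALSE]
  seen[queue] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue) > 0) {
    cur <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(steps))) {
      nb <- cur + steps[k, ]
      if (any(nb < 1) || any(nb > dm)) next
      if (m[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  sum(seen) == nrow(idx)
}

#' Generate synthetic block-design BOLD trials
#'
#' Builds `paradigm$n_trials` four-dimensional trial series on the given grid.
#' Active voxels follow `baseline * (1 + amplitude_pct/100 * r(t))` where
#' `r(t)` is the gamma-shaped stimulus regressor of [bold_regressor()]
#' (stimulation-period mean exactly 1); inactive voxels stay at baseline.
#' Independent Gaussian noise and an optional linear drift are added to every
#' voxel. All draws come from one generator seeded from `truth$seed`, so the
#' output is reproducible byte for byte.
#'
#' @param paradigm A [stim_paradigm()].
#' @param truth A [bold_truth()]; its `active_mask` must match `grid`.
#' @param grid Integer vector of volume dimensions, e.g. `c(80, 80, 4)`.
#' @param voxel_mm In-plane and slice voxel size (mm). Default
#'   `c(0.375, 0.375, 1)`.
#' @return An object of class `bold_trials`: list with `trials` (list of 4D
#'   arrays, x,y,z,image — full acquisition, discards included), `paradigm`,
#'   `voxel_mm` and the `truth` used.
#' @export
gen_bold_trials <- function(paradigm, truth, grid = dim(truth$active_mask),
                            voxel_mm = c(0.375, 0.375, 1)) {
  stopifnot(inherits(paradigm, "stim_paradigm"), inherits(truth, "bold_truth"))
  grid <- as.integer(grid)
  if (length(grid) == 2) grid <- c(grid, 1L)
  mdim <- dim(truth$active_mask)
  if (length(mdim) == 2) mdim <- c(mdim, 1L)
  if (!identical(as.integer(mdim), grid))
    stop("active_mask dimensions do not match the volume grid")
  n_img <- n_images_per_trial(paradigm)
  r <- bold_regressor(paradigm, discarded = FALSE)
  mask <- array(truth$active_mask, grid)
  nvox <- prod(grid)
  sd_abs <- truth$baseline * truth$noise_sd_pct / 100
  drift_per_img <- truth$drift_pct_per_min / 100 * truth$baseline *
    paradigm$tr_s / 60
  clean <- outer(ifelse(mask, truth$amplitude_pct / 100, 0), r) *
    truth$baseline + truth$baseline
  set.seed(truth$seed)
  trials <- vector("list", paradigm$n_trials)
  for (tr in seq_len(paradigm$n_trials)) {
    noise <- if (sd_abs > 0) stats::rnorm(nvox * n_img, sd = sd_abs) else 0
    vol <- clean + noise +
      rep((seq_len(n_img) - 1) * drift_per_img, each = nvox)
    trials[[tr]] <- array(vol, c(grid, n_img))
  }
  structure(list(trials = trials, paradigm = paradigm,
                 voxel_mm = voxel_mm, truth = truth),
            class = "bold_trials")
}

#' @export
print.bold_trials <- function(x, ...) {
  d <- dim(x$trials[[1]])
  cat("BOLD trial series:", length(x$trials), "trials of",
      paste(d[1:3], collapse = "x"), "voxels x", d[4], "images\n")
  invisible(x)
}

#' Rectangular activation mask helper
#'
#' @param grid Volume dimensions.
#' @param x,y,z Index ranges of the active block.
#' @return Logical array of dimension `grid`.
#' @export
rect_mask <- function(grid, x, y, z = 1) {
  grid <- as.integer(grid)
  if (length(grid) == 2) grid <- c(grid, 1L)
  m <- array(FALSE, grid)
  m[x, y, z] <- TRUE
  m
}
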