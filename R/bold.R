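#' Per-trial motion metric
#'
#' Maximum frame-to-frame displacement (in voxels) of the intensity-weighted
#' centre of mass of each image. A cheap surrogate for visual inspection of
#' residual head movement in pre-registered trial series: genuine motion
#' shifts the whole intensity distribution, while BOLD signal changes of a
#' few percent barely move it.
#'
#' @param vol4d 4D array (x, y, z, image).
#' @return Maximum frame-to-frame centre-of-mass displacement (voxels).
#' @export
motion_metric <- function(vol4d) {
  d <- dim(vol4d)
  stopifnot(length(d) == 4)
  nvox <- prod(d[1:3])
  grid <- arrayInd(seq_len(nvox), d[1:3])
  coms <- t(vapply(seq_len(d[4]), function(i) {
    w <- as.numeric(vol4d[, , , i])
    colSums(grid * w) / sum(w)
  }, numeric(3)))
  if (d[4] < 2) return(0)
  max(sqrt(rowSums(diff(coms)^2)))
}

#' Motion QC and trial averaging
#'
#' Drops trials whose motion metric exceeds `motion_limit`, discards the
#' leading `n_discard` images of every surviving trial, and averages the
#' survivors image-wise into one mean trial.
#'
#' @param trials A [gen_bold_trials()] result, or a list of 4D arrays plus a
#'   `paradigm`.
#' @param motion_limit Exclusion limit on the motion metric (voxels).
#'   Default 1.
#' @param paradigm Required when `trials` is a bare list.
#' @return List with `mean_trial` (4D array, post-discard images),
#'   `n_used`, `excluded` (indices of dropped trials), `motion` (per-trial
#'   metric), `paradigm`, `voxel_mm`.
#' @export
qc_and_average <- function(trials, motion_limit = 1, paradigm = NULL) {
  if (inherits(trials, "bold_trials")) {
    paradigm <- trials$paradigm
    voxel_mm <- trials$voxel_mm
    tl <- trials$trials
  } else {
    if (is.null(paradigm)) stop("paradigm required with a bare trial list")
    voxel_mm <- c(0.375, 0.375, 1)
    tl <- trials
  }
  motion <- vapply(tl, motion_metric, numeric(1))
  keep <- motion <= motion_limit
  if (!any(keep)) stop("all trials excluded by the motion limit")
  excluded <- which(!keep)
  if (length(excluded) > 0)
    message(length(excluded), " trial(s) excluded for motion: ",
            paste(excluded, collapse = ", "))
  nd <- paradigm$n_discard
  d <- dim(tl[[1]])
  img_keep <- seq.int(nd + 1L, d[4])
  acc <- 0
  for (i in which(keep)) acc <- acc + tl[[i]][, , , img_keep, drop = FALSE]
  list(mean_trial = acc / sum(keep), n_used = sum(keep),
       excluded = excluded, motion = motion, paradigm = paradigm,
       voxel_mm = voxel_mm)
}

#' Percent signal change of one voxel time course
#'
#' `100 * (x - baseline_mean) / baseline_mean`, with the baseline mean taken
#' over the post-discard baseline images; the baseline-period mean of the
#' result is 0% by construction.
#'
#' @param x Voxel time course on the post-discard image grid.
#' @param paradigm A [stim_paradigm()].
#' @return Percent-change series, or `NULL` when the baseline mean is not
#'   positive (voxel excluded).
#' @export
pct_change <- function(x, paradigm) {
  bidx <- baseline_image_idx(paradigm)
  if (length(bidx) < 2) stop("need at least 2 baseline images after discard")
  b <- mean(x[bidx])
  if (b <= 0) return(NULL)
  100 * (x - b) / b
}

# All-voxel percent-change matrix (voxels x images); voxels with
# non-positive baseline get NA rows.
pct_change_matrix <- function(mean_trial, paradigm) {
  d <- dim(mean_trial)
  nvox <- prod(d[1:3])
  m <- matrix(mean_trial, nvox, d[4])
  b <- rowMeans(m[, baseline_image_idx(paradigm), drop = FALSE])
  out <- 100 * (m - b) / b
  out[b <= 0, ] <- NA_real_
  out
}

#' Unsupervised SVM activation mapping
#'
#' Three-stage mapping of activated voxels from a mean trial, with no
#' training labels. Stage 1 treats mapping as outlier detection: a one-class
#' SVM (RBF kernel) is trained on every voxel's percent-change time course
#' and the rejected voxels become candidate actives. Stage 2 selects
#' prototypes: candidates in the top half by absolute correlation with the
#' stimulus reference regressor become positive prototypes, and an
#' equal-sized sample of clearly non-candidate voxels (absolute correlation
#' below the median) becomes the negative set. Stage 3 trains a two-class
#' SVM on the prototypes and reclassifies the candidates; the final map is
#' the candidates retained by the reclassifier. Both signal polarities are
#' detected because candidacy and prototype selection use absolute
#' correlation, so inverted (negative BOLD) regions map like positive ones.
#'
#' @param averaged A [qc_and_average()] result.
#' @param nu One-class rejection-rate parameter. Default 0.05.
#' @param proto_quantile Fraction of candidates (by absolute correlation)
#'   kept as positive prototypes. Default 0.5.
#' @param seed Seed for the negative-prototype sample. Default 1.
#' @return An object of class `activation_map`: list with `labels` (logical
#'   array over the volume grid), `correlation` (per-voxel correlation with
#'   the reference, same grid), `n_active`, `area_mm2` (per slice),
#'   `volume_mm3`, `voxel_mm`, `paradigm`.
#' @export
svm_activation_map <- function(averaged, nu = 0.05, proto_quantile = 0.5,
                               seed = 1) {
  mean_trial <- averaged$mean_trial
  paradigm <- averaged$paradigm
  d <- dim(mean_trial)
  nvox <- prod(d[1:3])
  if (nvox < 50) stop("need at least 50 voxels")
  pc <- pct_change_matrix(mean_trial, paradigm)
  ok <- stats::complete.cases(pc)
  ref <- bold_regressor(paradigm)
  cc <- rep(NA_real_, nvox)
  sds <- apply(pc[ok, , drop = FALSE], 1, stats::sd)
  cc[ok][sds > 0] <- suppressWarnings(
    stats::cor(t(pc[ok, , drop = FALSE][sds > 0, , drop = FALSE]), ref))
  empty_map <- function() structure(
    list(labels = array(FALSE, d[1:3]),
         correlation = array(cc, d[1:3]), n_active = 0L,
         area_mm2 = 0, volume_mm3 = 0, voxel_mm = averaged$voxel_mm,
         paradigm = paradigm), class = "activation_map")
  feats <- pc[ok, , drop = FALSE]
  if (nrow(feats) < 50 || all(apply(feats, 2, stats::sd) == 0))
    return(empty_map())
  oc <- e1071::svm(feats, y = NULL, type = "one-classification",
                   kernel = "radial", nu = nu, scale = FALSE)
  inlier <- stats::predict(oc, feats)
  cand <- which(ok)[!inlier]
  if (length(cand) < 2) return(empty_map())
  acc <- abs(cc)
  cut <- stats::quantile(acc[cand], probs = 1 - proto_quantile,
                         na.rm = TRUE, names = FALSE)
  pos <- cand[!is.na(acc[cand]) & acc[cand] >= cut]
  med <- stats::median(acc[ok], na.rm = TRUE)
  neg_pool <- setdiff(which(ok & !is.na(acc) & acc < med), cand)
  if (length(pos) < 2 || length(neg_pool) < 2) return(empty_map())
  set.seed(seed)
  neg <- sample(neg_pool, min(length(pos), length(neg_pool)))
  xtr <- pc[c(pos, neg), , drop = FALSE]
  ytr <- factor(rep(c("active", "inactive"), c(length(pos), length(neg))))
  tc <- e1071::svm(xtr, ytr, type = "C-classification", kernel = "radial",
                   scale = FALSE)
  pred <- stats::predict(tc, pc[cand, , drop = FALSE])
  active <- cand[pred == "active"]
  labels <- array(FALSE, d[1:3])
  labels[active] <- TRUE
  vx <- averaged$voxel_mm
  structure(list(labels = labels, correlation = array(cc, d[1:3]),
                 n_active = length(active),
                 area_mm2 = length(active) * vx[1] * vx[2],
                 volume_mm3 = length(active) * prod(vx),
                 voxel_mm = vx, paradigm = paradigm),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("Activation map:", x$n_active, "active voxels,",
      signif(x$area_mm2, 4), "mm^2 in-plane\n")
  invisible(x)
}

#' BOLD response magnitude, polarity and duration
#'
#' Averages the percent-change time courses of the mapped voxels into one
#' region time course; the magnitude is its mean over the stimulation
#' images, the polarity the sign of that magnitude, and the duration the
#' full width at half maximum of the time course around the extremum of the
#' absolute response (half level referenced to 0% baseline).
#'
#' @param map An [svm_activation_map()] result (non-empty).
#' @param averaged The matching [qc_and_average()] result.
#' @return An object of class `bold_metrics`: list with `magnitude_pct`,
#'   `polarity` (+1/-1), `duration_s`, `time_s`, `time_course` (region-mean
#'   percent change), `n_voxels`.
#' @export
response_metrics <- function(map, averaged) {
  stopifnot(inherits(map, "activation_map"))
  if (map$n_active == 0) stop("empty activation map: metrics undefined")
  paradigm <- averaged$paradigm
  pc <- pct_change_matrix(averaged$mean_trial, paradigm)
  tcs <- pc[as.vector(map$labels), , drop = FALSE]
  tc <- colMeans(tcs)
  mag <- mean(tc[stim_image_idx(paradigm)])
  tt <- image_times_s(paradigm)
  fw <- fwhm(tt, tc)
  structure(list(magnitude_pct = mag, polarity = sign(mag),
                 duration_s = fw$fwhm_s, time_s = tt, time_course = tc,
                 n_voxels = map$n_active),
            class = "bold_metrics")
}

#' @export
print.bold_metrics <- function(x, ...) {
  cat(sprintf("BOLD response: magnitude %.2f%%, duration %.1f s, %d voxels\n",
              x$magnitude_pct, x$duration_s, x$n_voxels))
  invisible(x)
}

#' Run the whole BOLD pipeline on a trial series
#'
#' Convenience wrapper: [qc_and_average()], [svm_activation_map()],
#' [response_metrics()].
#'
#' @inheritParams qc_and_average
#' @inheritParams svm_activation_map
#' @return List with `averaged`, `map`, `metrics`.
#' @export
bold_pipeline <- function(trials, motion_limit = 1, nu = 0.05,
                          proto_quantile = 0.5, seed = 1) {
  averaged <- qc_and_average(trials, motion_limit = motion_limit)
  map <- svm_activation_map(averaged, nu = nu,
                            proto_quantile = proto_quantile, seed = seed)
  metrics <- if (map$n_active > 0) response_metrics(map, averaged) else NULL
  list(averaged = averaged, map = map, metrics = metrics)
}
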