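#' Write BOLD trials as NIfTI-1 volumes
#'
#' One 4D NIfTI file per trial (`trial_01.nii.gz`, ...) with the voxel size
#' recorded in the header, plus a plain-text sidecar (`paradigm.yaml`) with
#' the paradigm and, when present, the generator ground truth.
#'
#' @param bt A [gen_bold_trials()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_bold_nifti <- function(bt, dir) {
  stopifnot(inherits(bt, "bold_trials"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(bt$trials))
  for (i in seq_along(bt$trials)) {
    paths[i] <- file.path(dir, sprintf("trial_%02d.nii.gz", i))
    img <- RNifti::asNifti(bt$trials[[i]],
                           pixdim = c(bt$voxel_mm, bt$paradigm$tr_s))
    RNifti::writeNifti(img, paths[i])
  }
  meta <- list(paradigm = unclass(bt$paradigm), voxel_mm = bt$voxel_mm)
  if (!is.null(bt$truth))
    meta$truth <- list(amplitude_pct = bt$truth$amplitude_pct,
                       noise_sd_pct = bt$truth$noise_sd_pct,
                       drift_pct_per_min = bt$truth$drift_pct_per_min,
                       baseline = bt$truth$baseline, seed = bt$truth$seed,
                       n_active = sum(bt$truth$active_mask))
  yaml::write_yaml(meta, file.path(dir, "paradigm.yaml"))
  invisible(c(paths, file.path(dir, "paradigm.yaml")))
}

#' Read BOLD trials written by [write_bold_nifti()]
#'
#' @param dir Directory containing `trial_*.nii(.gz)` and `paradigm.yaml`.
#' @return A `bold_trials` object (without ground truth).
#' @export
read_bold_nifti <- function(dir) {
  meta_path <- file.path(dir, "paradigm.yaml")
  if (!file.exists(meta_path)) stop("no paradigm.yaml in ", dir)
  meta <- yaml::read_yaml(meta_path)
  p <- meta$paradigm
  paradigm <- stim_paradigm(tr_s = p$tr_s, n_baseline = p$n_baseline,
                            n_stim = p$n_stim, n_post = p$n_post,
                            n_discard = p$n_discard, n_trials = p$n_trials,
                            stim_freq_hz = p$stim_freq_hz,
                            stim_delay_s = p$stim_delay_s)
  files <- sort(list.files(dir, pattern = "^trial_[0-9]+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no trial volumes in ", dir)
  trials <- lapply(files, function(f) {
    a <- tryCatch(RNifti::readNifti(f),
                  error = function(e) stop("corrupt NIfTI file ", f, ": ",
                                           conditionMessage(e)))
    array(as.numeric(a), dim(a))
  })
  structure(list(trials = trials, paradigm = paradigm,
                 voxel_mm = unlist(meta$voxel_mm), truth = NULL),
            class = "bold_trials")
}

#' Write an activation map as NIfTI volumes
#'
#' Two volumes: the active/inactive labels (`*_labels.nii.gz`, 0/1) and the
#' per-voxel correlation with the stimulus reference (`*_corr.nii.gz`).
#'
#' @param map An [svm_activation_map()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_map_nifti <- function(map, prefix) {
  stopifnot(inherits(map, "activation_map"))
  lp <- paste0(prefix, "_labels.nii.gz")
  cp <- paste0(prefix, "_corr.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map$labels),
                                           dim(map$labels)),
                                     pixdim = map$voxel_mm), lp)
  cc <- map$correlation
  cc[is.na(cc)] <- 0
  RNifti::writeNifti(RNifti::asNifti(cc, pixdim = map$voxel_mm), cp)
  invisible(c(lp, cp))
}

#' Write spike times and unit features as TSV
#'
#' @param sorted A [assign_units()] result (or compatible list).
#' @param spikes_path,features_path Output TSV paths.
#' @return Invisibly, the paths.
#' @export
write_spikes_tsv <- function(sorted, spikes_path, features_path) {
  rows <- do.call(rbind, lapply(seq_along(sorted$trains), function(u)
    if (length(sorted$trains[[u]]) > 0)
      data.frame(unit_id = u, time_s = sorted$trains[[u]]) else NULL))
  if (is.null(rows)) rows <- data.frame(unit_id = integer(0),
                                        time_s = numeric(0))
  utils::write.table(rows, spikes_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sorted$features, features_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(spikes_path, features_path))
}

#' Read a spike table written by [write_spikes_tsv()]
#'
#' @param path TSV with columns `unit_id`, `time_s`.
#' @return List of per-unit event-time vectors, named by unit id.
#' @export
read_spikes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("unit_id", "time_s") %in% names(df)))
  split(df$time_s, df$unit_id)
}

#' Write / read PO2 traces as TSV
#'
#' Long format: `time_s`, `po2_mmHg` and (for multi-trial data) `trial`.
#'
#' @param po2 A [gen_po2_trace()] result or a numeric vector.
#' @param path Output path.
#' @param time_s Sample times when `po2` is a bare vector.
#' @return Invisibly, `path`.
#' @export
write_po2_tsv <- function(po2, path, time_s = NULL) {
  if (inherits(po2, "po2_trials")) {
    df <- data.frame(time_s = rep(po2$time_s, ncol(po2$trials)),
                     po2_mmHg = as.vector(po2$trials),
                     trial = rep(seq_len(ncol(po2$trials)),
                                 each = nrow(po2$trials)))
  } else {
    if (is.null(time_s)) stop("time_s required with a bare vector")
    df <- data.frame(time_s = time_s, po2_mmHg = po2)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_po2_tsv
#' @return `read_po2_tsv`: a data frame with `time_s`, `po2_mmHg` and
#'   optionally `trial`.
#' @export
read_po2_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "po2_mmHg") %in% names(df)))
  df
}
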