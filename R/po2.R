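#' Downsample a PO2 trace to the BOLD sampling rate
#'
#' Block-mean downsampling: consecutive blocks of `fs * tr` samples are
#' averaged into one sample per TR (0.5 Hz at the default TR of 2 s), so the
#' oxygen trace can be compared image-for-image with the BOLD time course.
#'
#' @param po2 Numeric trace (mmHg) or a matrix with one trial per column.
#' @param fs_hz Input sampling rate. Default 20.
#' @param paradigm A [stim_paradigm()] supplying the TR. Default
#'   `stim_paradigm()`.
#' @return List with `time_s` (block-centre times) and `po2` (vector or
#'   matrix of block means).
#' @export
resample_to_bold <- function(po2, fs_hz = 20, paradigm = stim_paradigm()) {
  block <- fs_hz * paradigm$tr_s
  if (abs(block - round(block)) > 1e-9)
    stop("fs_hz * tr_s must be an integer number of samples")
  block <- as.integer(round(block))
  down <- function(x) {
    nb <- length(x) %/% block
    colMeans(matrix(x[seq_len(nb * block)], block, nb))
  }
  out <- if (is.matrix(po2)) apply(po2, 2, down) else down(po2)
  nb <- if (is.matrix(out)) nrow(out) else length(out)
  list(time_s = (seq_len(nb) - 0.5) * paradigm$tr_s, po2 = out)
}

#' PO2 baseline in mmHg
#'
#' Mean of the trace over a pre-stimulus window.
#'
#' @param po2 Numeric trace (mmHg).
#' @param time_s Sample times (s); default a uniform 20 Hz grid from 0.
#' @param window Numeric `c(start_s, end_s)` inside the trace.
#' @param fs_hz Sampling rate used to build the default time grid.
#' @return Baseline (mmHg).
#' @export
baseline_mmHg <- function(po2, window, time_s = NULL, fs_hz = 20) {
  if (is.null(time_s)) time_s <- (seq_along(po2) - 0.5) / fs_hz
  stopifnot(length(window) == 2, window[2] > window[1])
  if (window[1] < time_s[1] - 1 / fs_hz || window[2] > max(time_s) + 1 / fs_hz)
    stop("window falls outside the trace")
  sel <- time_s >= window[1] & time_s < window[2]
  if (!any(sel)) stop("window contains no samples")
  mean(po2[sel])
}

#' Classify PO2 trials and average their normalized responses
#'
#' Each trial is normalized to its own pre-stimulus baseline (= 100%); the
#' trial is `below_baseline` when its stimulation-period mean falls strictly
#' below 100% of that baseline and `above_baseline` otherwise (a mean of
#' exactly 100% counts as above). Two averages are reported, mirroring the
#' "after" vs "after + neg" presentation: over above-baseline trials only,
#' and over all trials.
#'
#' @param trials A [gen_po2_trace()] result, or a samples x trials matrix
#'   with `paradigm` and `fs_hz` supplied.
#' @param paradigm,fs_hz Required when `trials` is a bare matrix.
#' @return An object of class `po2_summary`: data frame `per_trial`
#'   (`trial`, `class`, `response_pct`), `mean_above_only`,
#'   `mean_all_trials`, `n_above`, `n_below`, and `norm_trials` (normalized
#'   traces, % of baseline).
#' @export
classify_and_average <- function(trials, paradigm = NULL, fs_hz = NULL) {
  if (inherits(trials, "po2_trials")) {
    paradigm <- trials$paradigm
    fs_hz <- trials$fs_hz
    m <- trials$trials
    time_s <- trials$time_s
  } else {
    if (is.null(paradigm) || is.null(fs_hz))
      stop("paradigm and fs_hz required with a bare matrix")
    m <- as.matrix(trials)
    time_s <- (seq_len(nrow(m)) - 0.5) / fs_hz
  }
  if (ncol(m) < 1) stop("at least one trial is required")
  t_base <- paradigm$n_baseline * paradigm$tr_s
  t_stim_end <- t_base + paradigm$n_stim * paradigm$tr_s
  base_sel <- time_s < t_base
  stim_sel <- time_s >= t_base & time_s < t_stim_end
  norm <- apply(m, 2, function(x) 100 * x / mean(x[base_sel]))
  resp <- colMeans(norm[stim_sel, , drop = FALSE])
  cls <- ifelse(resp < 100, "below_baseline", "above_baseline")
  above <- cls == "above_baseline"
  structure(list(
    per_trial = data.frame(trial = seq_len(ncol(m)), class = cls,
                           response_pct = resp),
    mean_above_only = if (any(above)) mean(resp[above]) else NA_real_,
    mean_all_trials = mean(resp),
    n_above = sum(above), n_below = sum(!above),
    norm_trials = norm, time_s = time_s),
    class = "po2_summary")
}

#' @export
print.po2_summary <- function(x, ...) {
  cat(sprintf(
    "PO2 summary: %d above / %d below baseline; above-only mean %.2f%%, all-trial mean %.2f%% of baseline\n",
    x$n_above, x$n_below, x$mean_above_only, x$mean_all_trials))
  invisible(x)
}
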