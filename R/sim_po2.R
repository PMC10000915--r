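#' Ground truth for synthetic tissue-oxygen traces
#'
#' @param baseline_mmHg Pre-stimulus PO2 baseline (mmHg). Default 25.12.
#' @param response_amplitude_pct Plateau response amplitude during
#'   stimulation, signed, in percent of baseline (so `+4.71` gives a
#'   104.71%-of-baseline plateau). Either a scalar applied to every trial or
#'   one value per trial, which allows transient below-baseline trials.
#' @param noise_sd_mmHg Gaussian noise SD (mmHg). Default 0.5.
#' @param fs_hz Sampling rate. Default 20.
#' @param seed RNG seed (required).
#' @return An object of class `po2_truth`.
#' @export
po2_truth <- function(baseline_mmHg = 25.12, response_amplitude_pct = 4.71,
                      noise_sd_mmHg = 0.5, fs_hz = 20, seed) {
  if (missing(seed)) stop("seed is required")
  if (baseline_mmHg <= 0) stop("baseline_mmHg must be positive")
  if (noise_sd_mmHg < 0) stop("noise_sd_mmHg must be >= 0")
  structure(list(baseline_mmHg = baseline_mmHg,
                 response_amplitude_pct = response_amplitude_pct,
                 noise_sd_mmHg = noise_sd_mmHg, fs_hz = fs_hz,
                 seed = as.integer(seed)),
            class = "po2_truth")
}

#' Generate synthetic PO2 trial traces
#'
#' One 20 Hz trace per trial following the paradigm timing: the trace sits at
#' `baseline_mmHg` outside the stimulation period and at
#' `baseline * (1 + amplitude/100)` during it (a boxcar response, so the
#' noiseless plateau and the stimulation-period mean both equal the amplitude
#' parameter exactly), plus Gaussian noise. Per-trial amplitudes allow
#' stimulus-locked below-baseline deflections in a subset of trials.
#'
#' @param paradigm A [stim_paradigm()]; only its period durations and trial
#'   count are used (no image discarding applies to the oxygen electrode).
#' @param truth A [po2_truth()].
#' @return An object of class `po2_trials`: list with `time_s` (one trial's
#'   sample times), `trials` (matrix, samples x trials, mmHg), `fs_hz`,
#'   `paradigm`, `truth`.
#' @export
gen_po2_trace <- function(paradigm, truth) {
  stopifnot(inherits(paradigm, "stim_paradigm"), inherits(truth, "po2_truth"))
  fs <- truth$fs_hz
  t_base <- paradigm$n_baseline * paradigm$tr_s
  t_stim <- paradigm$n_stim * paradigm$tr_s
  n <- round(trial_duration_s(paradigm) * fs)
  tt <- (seq_len(n) - 0.5) / fs
  shape <- as.numeric(tt >= t_base & tt < t_base + t_stim)
  amp <- truth$response_amplitude_pct
  if (length(amp) == 1) amp <- rep(amp, paradigm$n_trials)
  if (length(amp) != paradigm$n_trials)
    stop("response_amplitude_pct must be scalar or one value per trial")
  set.seed(truth$seed)
  trials <- vapply(seq_len(paradigm$n_trials), function(k) {
    clean <- truth$baseline_mmHg * (1 + amp[k] / 100 * shape)
    if (truth$noise_sd_mmHg > 0)
      clean + stats::rnorm(n, sd = truth$noise_sd_mmHg) else clean
  }, numeric(n))
  structure(list(time_s = tt, trials = trials, fs_hz = fs,
                 paradigm = paradigm, truth = truth),
            class = "po2_trials")
}

#' @export
print.po2_trials <- function(x, ...) {
  cat("PO2 trial traces:", ncol(x$trials), "trials of", nrow(x$trials),
      "samples at", x$fs_hz, "Hz, baseline",
      x$truth$baseline_mmHg, "mmHg\n")
  invisible(x)
}
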