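#' Block-design stimulation paradigm
#'
#' Describes the trial timing grammar shared by all modalities: a non-stimulus
#' baseline period, a stimulation period and a post-stimulus period, each
#' expressed as image counts at a fixed repetition time (TR). The leading
#' `n_discard` images of every trial are acquired while the MR signal reaches
#' equilibrium and are dropped before analysis.
#'
#' @param tr_s Seconds per image (TR). Default 2.
#' @param n_baseline Baseline image count. Default 25 (= 50 s at TR 2 s).
#' @param n_stim Stimulation image count. Default 20 (= 40 s).
#' @param n_post Post-stimulus image count. Default 20 (= 40 s).
#' @param n_discard Leading images dropped per trial. Default 5.
#' @param n_trials Number of trials per experiment. Default 10.
#' @param stim_freq_hz Whisker vibration frequency in Hz (metadata only).
#'   Default 50.
#' @param stim_delay_s Delay of stimulus onset from the MR acquisition trigger,
#'   used when aligning electrophysiological events; the gradient pulses of the
#'   triggering image would otherwise contaminate the earliest evoked spikes.
#'   Default 0.15.
#'
#' @return An object of class `stim_paradigm`.
#' @examples
#' p <- stim_paradigm()
#' trial_duration_s(p)   # 130 s
#' @export
stim_paradigm <- function(tr_s = 2, n_baseline = 25L, n_stim = 20L,
                          n_post = 20L, n_discard = 5L, n_trials = 10L,
                          stim_freq_hz = 50, stim_delay_s = 0.15) {
  counts <- c(n_baseline = n_baseline, n_stim = n_stim, n_post = n_post,
              n_trials = n_trials)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("image and trial counts must be positive integers")
  if (n_discard < 0 || n_discard != round(n_discard))
    stop("n_discard must be a non-negative integer")
  if (n_discard >= n_baseline)
    stop("n_discard must be smaller than n_baseline")
  if (tr_s <= 0) stop("tr_s must be positive")
  structure(list(tr_s = tr_s,
                 n_baseline = as.integer(n_baseline),
                 n_stim = as.integer(n_stim),
                 n_post = as.integer(n_post),
                 n_discard = as.integer(n_discard),
                 n_trials = as.integer(n_trials),
                 stim_freq_hz = stim_freq_hz,
                 stim_delay_s = stim_delay_s),
            class = "stim_paradigm")
}

#' @export
print.stim_paradigm <- function(x, ...) {
  cat("Block-design paradigm:", x$n_baseline, "baseline +", x$n_stim,
      "stim +", x$n_post, "post images, TR", x$tr_s, "s,",
      x$n_trials, "trials,", x$n_discard, "leading images discarded\n")
  invisible(x)
}

#' Total images per trial (before discarding)
#' @param paradigm A [stim_paradigm()].
#' @return Integer image count.
#' @export
n_images_per_trial <- function(paradigm) {
  paradigm$n_baseline + paradigm$n_stim + paradigm$n_post
}

#' Trial duration in seconds
#' @inheritParams n_images_per_trial
#' @return Seconds.
#' @export
trial_duration_s <- function(paradigm) {
  n_images_per_trial(paradigm) * paradigm$tr_s
}

#' Image indices of the stimulation period
#'
#' @inheritParams n_images_per_trial
#' @param discarded Logical; if `TRUE` (default) indices refer to the trial
#'   after the leading `n_discard` images were dropped, otherwise to the raw
#'   acquisition.
#' @return Integer vector of 1-based image indices.
#' @export
stim_image_idx <- function(paradigm, discarded = TRUE) {
  off <- if (discarded) paradigm$n_baseline - paradigm$n_discard
         else paradigm$n_baseline
  seq.int(off + 1L, off + paradigm$n_stim)
}

#' Image indices of the baseline period
#' @inheritParams stim_image_idx
#' @return Integer vector of 1-based image indices.
#' @export
baseline_image_idx <- function(paradigm, discarded = TRUE) {
  n <- if (discarded) paradigm$n_baseline - paradigm$n_discard
       else paradigm$n_baseline
  seq_len(n)
}

#' Stimulus onset times for every trial
#'
#' Onset of the stimulation period for each trial, in seconds from the start
#' of the recording, including the configured trigger delay.
#'
#' @inheritParams n_images_per_trial
#' @param include_delay Apply `stim_delay_s`? Default `TRUE`.
#' @return Numeric vector, one onset per trial.
#' @export
stim_onsets_s <- function(paradigm, include_delay = TRUE) {
  starts <- (seq_len(paradigm$n_trials) - 1L) * trial_duration_s(paradigm)
  on <- starts + paradigm$n_baseline * paradigm$tr_s
  if (include_delay) on <- on + paradigm$stim_delay_s
  on
}

#' Mid-image acquisition times within one trial
#' @inheritParams stim_image_idx
#' @return Numeric vector of times (s) at image centres, 0 = trial start
#'   (raw acquisition clock even when `discarded`).
#' @export
image_times_s <- function(paradigm, discarded = TRUE) {
  idx <- if (discarded) seq.int(paradigm$n_discard + 1L, n_images_per_trial(paradigm))
         else seq_len(n_images_per_trial(paradigm))
  (idx - 0.5) * paradigm$tr_s
}
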