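#' Ground truth for synthetic extracellular recordings
#'
#' Describes a set of single units (each with a stereotyped action-potential
#' waveform and a piecewise-homogeneous Poisson firing rate), the Gaussian
#' background noise, and the periodic gradient-artifact blocks contaminating
#' the trace during image acquisition.
#'
#' @param units Data frame with one row per unit and columns `duration_ms`
#'   (peak-to-valley time of the action potential), `amplitude` (peak height,
#'   volts), `rate` (baseline firing rate, spikes/s), `stim_mult`
#'   (rate multiplier during stimulation periods) and `drug_mult` (rate
#'   multiplier after drug injection).
#' @param noise_sd Background noise SD (volts). Default 10e-6.
#' @param artifact_period_s Gradient-block repetition period (s); one block
#'   per acquired image, so this defaults to the TR, 2 s.
#' @param artifact_width_s Gradient-block width (s). Default 0.030.
#' @param artifact_amplitude Artifact amplitude (volts). Default 500e-6.
#' @param fs_hz Sampling rate. Default 32000.
#' @param seed RNG seed (required).
#' @return An object of class `ephys_truth`.
#' @export
ephys_truth <- function(units, noise_sd = 10e-6, artifact_period_s = 2,
                        artifact_width_s = 0.030,
                        artifact_amplitude = 500e-6, fs_hz = 32000, seed) {
  if (missing(seed)) stop("seed is required")
  units <- as.data.frame(units)
  need <- c("duration_ms", "amplitude", "rate", "stim_mult", "drug_mult")
  if (!all(need %in% names(units)))
    stop("units needs columns: ", paste(need, collapse = ", "))
  if (any(units$rate < 0)) stop("firing rates must be >= 0")
  if (any(units$stim_mult < 0) || any(units$drug_mult < 0))
    stop("rate multipliers must be >= 0")
  if (any(units$duration_ms <= 0)) stop("AP durations must be positive")
  if (artifact_width_s >= artifact_period_s)
    stop("artifact_width_s must be smaller than artifact_period_s")
  structure(list(units = units, noise_sd = noise_sd,
                 artifact_period_s = artifact_period_s,
                 artifact_width_s = artifact_width_s,
                 artifact_amplitude = artifact_amplitude,
                 fs_hz = fs_hz, seed = as.integer(seed)),
            class = "ephys_truth")
}

#' Biphasic action-potential template
#'
#' Difference of two Gaussians: a positive peak at time 0 followed by a
#' negative valley at `duration_ms` later. The peak-to-valley time is the
#' waveform feature that drives unit sorting and interneuron classification.
#'
#' @param duration_ms Peak-to-valley time (ms).
#' @param amplitude Peak height (volts).
#' @param fs_hz Sampling rate.
#' @param valley_frac Valley depth as a fraction of the peak. Default 0.6.
#' @return List with `w` (waveform samples) and `peak_idx` (index of the
#'   positive peak within `w`).
#' @export
spike_template <- function(duration_ms, amplitude, fs_hz,
                           valley_frac = 0.6) {
  stopifnot(duration_ms > 0, amplitude > 0)
  dur_s <- duration_ms / 1000
  sig_p <- dur_s / 4
  sig_v <- dur_s / 2.5
  tt <- seq(-3 * sig_p, dur_s + 3 * sig_v, by = 1 / fs_hz)
  w <- amplitude * (exp(-tt^2 / (2 * sig_p^2)) -
                    valley_frac * exp(-(tt - dur_s)^2 / (2 * sig_v^2)))
  list(w = w, peak_idx = which.max(w))
}

#' Piecewise-homogeneous Poisson spike times
#'
#' @param duration_s Recording length (s).
#' @param rate Baseline rate (spikes/s).
#' @param epochs Optional data frame with `start_s`, `end_s`, `mult`: within
#'   each interval the rate is `rate * mult`. Intervals must not overlap.
#' @param refractory_s Minimum interval enforced between events. Default 0.002.
#' @return Sorted numeric vector of spike times (s).
#' @export
gen_spike_times <- function(duration_s, rate, epochs = NULL,
                            refractory_s = 0.002) {
  stopifnot(duration_s > 0, rate >= 0)
  rate_at <- function(t) {
    r <- rep(rate, length(t))
    if (!is.null(epochs)) for (i in seq_len(nrow(epochs))) {
      sel <- t >= epochs$start_s[i] & t < epochs$end_s[i]
      r[sel] <- rate * epochs$mult[i]
    }
    r
  }
  rmax <- rate * max(1, if (is.null(epochs)) 1 else max(epochs$mult))
  if (rmax == 0) return(numeric(0))
  # thinning of a homogeneous process at the max rate
  n_cand <- stats::rpois(1, rmax * duration_s)
  cand <- sort(stats::runif(n_cand, 0, duration_s))
  keep <- stats::runif(n_cand) < rate_at(cand) / rmax
  times <- cand[keep]
  if (length(times) > 1) {
    ok <- c(TRUE, diff(times) >= refractory_s)
    # iterate: removing an event can expose a new short interval
    while (!all(ok)) {
      times <- times[ok]
      ok <- c(TRUE, diff(times) >= refractory_s)
    }
  }
  times
}

#' Generate a raw synthetic extracellular trace
#'
#' Builds a 32 kHz voltage trace as the sum of Gaussian background noise,
#' stereotyped biphasic waveforms placed at Poisson event times for every
#' unit (rates switch by the stimulation and drug multipliers inside the
#' labelled epochs), and periodic gradient-artifact blocks. The true event
#' times of every unit are returned exactly alongside the trace.
#'
#' @param truth An [ephys_truth()].
#' @param duration_s Recording length (s).
#' @param stim_epochs Optional data frame (`start_s`, `end_s`) of stimulation
#'   periods (rate multiplied by `stim_mult` inside).
#' @param drug_onset_s Optional time after which `drug_mult` applies.
#'   Default `NULL` (never).
#' @param artifacts Add gradient-artifact blocks? Default `TRUE`.
#' @return An object of class `ephys_recording`: list with `trace` (volts),
#'   `fs_hz`, `true_spikes` (data frame `unit_id`, `time_s`),
#'   `artifact_intervals` (data frame `start_s`, `end_s`), `truth`.
#' @export
gen_raw_ephys <- function(truth, duration_s, stim_epochs = NULL,
                          drug_onset_s = NULL, artifacts = TRUE) {
  stopifnot(inherits(truth, "ephys_truth"))
  if (duration_s <= 0) stop("duration_s must be positive")
  fs <- truth$fs_hz
  n <- round(duration_s * fs)
  set.seed(truth$seed)
  trace <- if (truth$noise_sd > 0) stats::rnorm(n, sd = truth$noise_sd)
           else numeric(n)
  all_times <- list()
  for (u in seq_len(nrow(truth$units))) {
    ut <- truth$units[u, ]
    ep <- NULL
    if (!is.null(stim_epochs) && nrow(stim_epochs) > 0)
      ep <- data.frame(start_s = stim_epochs$start_s,
                       end_s = stim_epochs$end_s, mult = ut$stim_mult)
    if (!is.null(drug_onset_s)) {
      # drug multiplier applies multiplicatively after onset; represent the
      # post-onset non-stimulus stretch as its own epoch
      base_ep <- data.frame(start_s = drug_onset_s, end_s = duration_s,
                            mult = ut$drug_mult)
      if (!is.null(ep)) {
        post <- ep$start_s >= drug_onset_s
        ep$mult[post] <- ep$mult[post] * ut$drug_mult
        ep <- rbind(base_ep, ep)     # later rows override inside stim epochs
      } else ep <- base_ep
    }
    times <- gen_spike_times(duration_s, ut$rate, epochs = ep)
    tmpl <- spike_template(ut$duration_ms, ut$amplitude, fs)
    idx0 <- round(times * fs) - tmpl$peak_idx + 1L
    for (i in seq_along(idx0)) {
      a <- idx0[i]; b <- a + length(tmpl$w) - 1L
      sa <- max(a, 1L); sb <- min(b, n)
      if (sa <= sb)
        trace[sa:sb] <- trace[sa:sb] + tmpl$w[(sa - a + 1L):(sb - a + 1L)]
    }
    all_times[[u]] <- data.frame(unit_id = u, time_s = times)
  }
  art <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (artifacts && truth$artifact_amplitude > 0) {
    starts <- seq(0, duration_s - truth$artifact_width_s,
                  by = truth$artifact_period_s)
    art <- data.frame(start_s = starts,
                      end_s = starts + truth$artifact_width_s)
    wsamp <- round(truth$artifact_width_s * fs)
    burst_t <- seq_len(wsamp) / fs
    # dense alternating block: |burst| stays at the artifact amplitude
    # throughout, the way a saturated gradient-switching artifact does
    burst <- truth$artifact_amplitude *
      sign(sin(2 * pi * 1000 * burst_t) + 0.5)
    for (s0 in starts) {
      a <- round(s0 * fs) + 1L
      b <- min(a + wsamp - 1L, n)
      trace[a:b] <- trace[a:b] + burst[seq_len(b - a + 1L)]
    }
  }
  structure(list(trace = trace, fs_hz = fs,
                 true_spikes = do.call(rbind, all_times),
                 artifact_intervals = art, duration_s = duration_s,
                 truth = truth),
            class = "ephys_recording")
}

#' @export
print.ephys_recording <- function(x, ...) {
  cat("Extracellular recording:", x$duration_s, "s at", x$fs_hz, "Hz,",
      nrow(x$truth$units), "units,",
      nrow(x$true_spikes), "true spikes,",
      nrow(x$artifact_intervals), "artifact blocks\n")
  invisible(x)
}

#' Gaussian-rate population for resting-state simulations
#'
#' Draws per-unit baseline rates from a gamma distribution with the given
#' population mean and SD, the positive, right-skewed shape typical of
#' spontaneous cortical firing rates.
#'
#' @param n_units Number of units.
#' @param mean_rate Population mean rate (spikes/s). Default 3.21.
#' @param sd_rate Across-unit SD (spikes/s). Default 0.98.
#' @return Numeric vector of rates.
#' @export
draw_unit_rates <- function(n_units, mean_rate = 3.21, sd_rate = 0.98) {
  stopifnot(n_units >= 1, mean_rate > 0, sd_rate > 0)
  shape <- (mean_rate / sd_rate)^2
  stats::rgamma(n_units, shape = shape, rate = shape / mean_rate)
}
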