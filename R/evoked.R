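#' Peri-event histogram for one unit
#'
#' Bins event times relative to each stimulus onset and averages the binned
#' rates over trials. Optionally normalises to the pre-stimulus baseline
#' (mean of bins ending at or before onset), so the baseline level is 100%.
#'
#' @param times Event times (s, recording clock).
#' @param onsets Stimulus-onset times (s); at least one.
#' @param window Numeric `c(before_s, after_s)` relative to onset.
#'   Default `c(-10, 50)`.
#' @param bin_width Bin width (s). Default 1 (the 1 Hz unit-rate convention).
#' @param normalize Express rates as percent of the pre-stimulus baseline?
#'   Default `FALSE`.
#' @return An object of class `peh`: list with `edges` (bin edges, s),
#'   `rate` (spikes/s per bin, trial-averaged), `norm_rate` (% of baseline,
#'   `NULL` unless baseline is defined), `n_events`, `n_trials`,
#'   `normalized`.
#' @export
build_peh <- function(times, onsets, window = c(-10, 50), bin_width = 1,
                      normalize = FALSE) {
  if (length(onsets) < 1) stop("at least one stimulus onset is required")
  stopifnot(length(window) == 2, window[2] > window[1], bin_width > 0)
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  nb <- length(edges) - 1
  counts <- numeric(nb)
  n_events <- 0L
  for (on in onsets) {
    rel <- times - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    n_events <- n_events + length(rel)
    if (length(rel) > 0)
      counts <- counts + graphics::hist(rel, breaks = edges, plot = FALSE,
                                        right = FALSE)$counts
  }
  widths <- diff(edges)
  rate <- counts / (length(onsets) * widths)
  base_bins <- which(edges[-1] <= 0)
  norm_rate <- NULL
  if (length(base_bins) > 0) {
    base_mean <- mean(rate[base_bins])
    if (base_mean > 0) norm_rate <- 100 * rate / base_mean
  }
  structure(list(edges = edges, rate = rate, norm_rate = norm_rate,
                 n_events = n_events, n_trials = length(onsets),
                 normalized = normalize),
            class = "peh")
}

#' @export
print.peh <- function(x, ...) {
  cat("Peri-event histogram:", length(x$rate), "bins over",
      x$n_trials, "trials,", x$n_events, "events\n")
  invisible(x)
}

# Mean rate (or normalized rate) of a PEH over bins whose centres fall in
# [from_s, to_s) relative to onset.
peh_window_mean <- function(peh, from_s, to_s, normalized = FALSE) {
  ctr <- (peh$edges[-1] + peh$edges[-length(peh$edges)]) / 2
  sel <- ctr >= from_s & ctr < to_s
  y <- if (normalized) peh$norm_rate else peh$rate
  if (is.null(y)) return(NA_real_)
  mean(y[sel])
}

#' Classify a unit's stimulus response from its peri-event histogram
#'
#' A unit is excitatory when its stimulation-period mean rate exceeds the
#' pre-stimulus baseline mean by more than `sd_mult` baseline SDs, inhibitory
#' when it falls below by the same margin, and non-responsive otherwise. The
#' response magnitude is the stimulation-period mean expressed as percent of
#' the baseline (100% = no change); it is only defined for responsive units.
#'
#' @param peh A [build_peh()] result with at least 5 baseline bins.
#' @param stim_duration_s Stimulation-period length (s). Default 40.
#' @param sd_mult Baseline-SD multiplier for the decision bound. Default 2.
#' @param unit_id Optional id carried into the summary.
#' @return An object of class `response_summary`: list with `unit_id`,
#'   `polarity` (`"excitatory"`, `"inhibitory"`, `"none"`),
#'   `magnitude_pct_of_baseline` (`NA` when polarity is `"none"`),
#'   `baseline_mean`, `baseline_sd`, `stim_mean`.
#' @export
classify_response <- function(peh, stim_duration_s = 40, sd_mult = 2,
                              unit_id = NA) {
  stopifnot(inherits(peh, "peh"))
  base_bins <- which(peh$edges[-1] <= 0)
  if (length(base_bins) < 5) stop("at least 5 baseline bins are required")
  base_mean <- mean(peh$rate[base_bins])
  base_sd <- stats::sd(peh$rate[base_bins])
  stim_mean <- peh_window_mean(peh, 0, stim_duration_s)
  polarity <- "none"
  if (base_sd == 0 && base_mean == 0) {
    polarity <- if (stim_mean > 0) "excitatory" else "none"
  } else if (stim_mean > base_mean + sd_mult * base_sd) {
    polarity <- "excitatory"
  } else if (stim_mean < base_mean - sd_mult * base_sd) {
    polarity <- "inhibitory"
  }
  mag <- if (polarity == "none" || base_mean <= 0) NA_real_
         else 100 * stim_mean / base_mean
  structure(list(unit_id = unit_id, polarity = polarity,
                 magnitude_pct_of_baseline = mag,
                 baseline_mean = base_mean, baseline_sd = base_sd,
                 stim_mean = stim_mean),
            class = "response_summary")
}

#' Pre vs post comparison of evoked-response polarity and magnitude
#'
#' Matches units by id, labels transitions (`newly_acquired` for units
#' excitatory only after injection, `abolished` for units excitatory only
#' before), and for units excitatory in both conditions computes the mean
#' percent change in normalized response magnitude (mean of per-unit
#' post/pre ratios) with a two-tailed paired t-test on the magnitudes.
#' Transition units are excluded from the magnitude-change mean because
#' their pre/post ratio is undefined.
#'
#' @param summaries_pre,summaries_post Lists of [classify_response()] results
#'   with matching `unit_id` sets.
#' @return List with `n_pairs`, `mean_change_pct`, `t_statistic`, `p_value`,
#'   `transitions` (data frame `unit_id`, `status`), and the per-unit
#'   `pre_magnitude`, `post_magnitude` used.
#' @export
compare_magnitudes <- function(summaries_pre, summaries_post) {
  ids_pre <- vapply(summaries_pre, function(s) s$unit_id, numeric(1))
  ids_post <- vapply(summaries_post, function(s) s$unit_id, numeric(1))
  common <- intersect(ids_pre, ids_post)
  status <- character(0); sid <- numeric(0)
  pre_mag <- post_mag <- numeric(0)
  for (id in common) {
    sp <- summaries_pre[[match(id, ids_pre)]]
    sq <- summaries_post[[match(id, ids_post)]]
    exc_pre <- sp$polarity == "excitatory"
    exc_post <- sq$polarity == "excitatory"
    if (exc_pre && exc_post) {
      pre_mag <- c(pre_mag, sp$magnitude_pct_of_baseline)
      post_mag <- c(post_mag, sq$magnitude_pct_of_baseline)
      sid <- c(sid, id); status <- c(status, "paired")
    } else if (!exc_pre && exc_post) {
      sid <- c(sid, id); status <- c(status, "newly_acquired")
      pre_mag <- c(pre_mag, NA); post_mag <- c(post_mag, NA)
    } else if (exc_pre && !exc_post) {
      sid <- c(sid, id); status <- c(status, "abolished")
      pre_mag <- c(pre_mag, NA); post_mag <- c(post_mag, NA)
    }
  }
  paired <- status == "paired"
  if (sum(paired) < 2) stop("fewer than 2 excitatory pre/post pairs")
  pm <- pre_mag[paired]; qm <- post_mag[paired]
  change <- 100 * (qm - pm) / pm
  d <- qm - pm
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    tt <- list(statistic = 0, p.value = if (all(d == 0)) 1 else NA_real_)
  } else {
    ht <- stats::t.test(qm, pm, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(n_pairs = sum(paired), mean_change_pct = mean(change),
       t_statistic = tt$statistic, p_value = tt$p.value,
       transitions = data.frame(unit_id = sid, status = status),
       pre_magnitude = pm, post_magnitude = qm)
}

#' Bin-wise population-average histogram
#'
#' Pools the normalized histograms of several units of one cell type into an
#' average population histogram (bin-wise mean across units).
#'
#' @param pehs List of [build_peh()] results on identical bin grids, each
#'   with a defined normalized rate.
#' @return A `peh` whose `norm_rate` is the bin-wise mean; `rate` is the
#'   bin-wise mean raw rate.
#' @export
population_peh <- function(pehs) {
  stopifnot(length(pehs) >= 1)
  edges <- pehs[[1]]$edges
  for (p in pehs) if (!isTRUE(all.equal(p$edges, edges)))
    stop("all histograms must share one bin grid")
  rate <- rowMeans(vapply(pehs, function(p) p$rate,
                          numeric(length(edges) - 1)))
  nr <- lapply(pehs, function(p) p$norm_rate)
  norm_rate <- if (any(vapply(nr, is.null, logical(1)))) NULL
               else rowMeans(do.call(cbind, nr))
  structure(list(edges = edges, rate = rate, norm_rate = norm_rate,
                 n_events = sum(vapply(pehs, function(p) p$n_events,
                                       numeric(1))),
                 n_trials = pehs[[1]]$n_trials, normalized = TRUE),
            class = "peh")
}
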