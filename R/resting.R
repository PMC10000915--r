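#' Firing rate within a time window
#'
#' Spike counts are binned at 1 Hz and the per-second rates averaged — the
#' convention used to smooth single-unit rate estimates before comparing them
#' across windows. For a window spanning a whole number of seconds this
#' equals count/duration; a fractional trailing bin is weighted by its
#' length.
#'
#' @param times Event times (s) of one unit.
#' @param window Numeric `c(start_s, end_s)`, `end > start`.
#' @return Rate in spikes/s.
#' @export
rate_in_window <- function(times, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start_s, end_s) with end > start")
  dur <- window[2] - window[1]
  sel <- times >= window[1] & times < window[2]
  edges <- seq(window[1], window[2], by = 1)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  counts <- graphics::hist(times[sel], breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  sum(counts) / dur
}

#' Classify a unit's firing-rate change into three bins
#'
#' A unit counts as increased only when its after-rate exceeds the
#' before-rate by more than the threshold fraction, decreased only when it
#' falls short by more than the threshold; equality at the boundary is
#' `no_change` (strict inequalities).
#'
#' @param before Rate before injection (spikes/s), must be > 0.
#' @param after Rate after injection (spikes/s).
#' @param threshold_frac Change threshold as a fraction of `before`
#'   (0.30 or 0.10 in the standard analysis), in (0, 1).
#' @return One of `"increase"`, `"decrease"`, `"no_change"`.
#' @export
classify_change <- function(before, after, threshold_frac) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  if (before <= 0) stop("before-rate must be positive (unit excluded)")
  if (after > before * (1 + threshold_frac)) "increase"
  else if (after < before * (1 - threshold_frac)) "decrease"
  else "no_change"
}

#' Three-bin change distribution over a set of units
#'
#' @param before,after Vectors of per-unit rates (spikes/s).
#' @param threshold_frac Change threshold fraction.
#' @param window_label Optional label for the after-window.
#' @return An object of class `change_distribution`: counts
#'   `n_increase`, `n_decrease`, `n_no_change`, plus `n_excluded` (units with
#'   zero before-rate), `threshold_frac`, `window_label`, and the per-unit
#'   `bins`.
#' @export
change_distribution <- function(before, after, threshold_frac,
                                window_label = NA_character_) {
  stopifnot(length(before) == length(after))
  bins <- rep(NA_character_, length(before))
  ok <- before > 0
  bins[ok] <- mapply(classify_change, before[ok], after[ok],
                     MoreArgs = list(threshold_frac = threshold_frac))
  structure(list(n_increase = sum(bins == "increase", na.rm = TRUE),
                 n_decrease = sum(bins == "decrease", na.rm = TRUE),
                 n_no_change = sum(bins == "no_change", na.rm = TRUE),
                 n_excluded = sum(!ok),
                 threshold_frac = threshold_frac,
                 window_label = window_label,
                 bins = bins),
            class = "change_distribution")
}

#' @export
print.change_distribution <- function(x, ...) {
  n <- x$n_increase + x$n_decrease + x$n_no_change
  cat(sprintf(
    "Change distribution (threshold %.0f%%%s): %d increase (%.0f%%), %d decrease (%.0f%%), %d no change; %d excluded\n",
    100 * x$threshold_frac,
    if (is.na(x$window_label)) "" else paste0(", ", x$window_label),
    x$n_increase, 100 * x$n_increase / n,
    x$n_decrease, 100 * x$n_decrease / n, x$n_no_change, x$n_excluded))
  invisible(x)
}

#' Resting-state change dynamics across post-injection windows
#'
#' Computes the three-bin change distribution in consecutive five-minute
#' windows after injection and tests their homogeneity with a Pearson
#' chi-squared test (windows x bins contingency table, no continuity
#' correction). Units whose recording does not cover a window are excluded
#' from that window only.
#'
#' @param trains List of per-unit event-time vectors (s, recording clock).
#' @param injection_s Injection time (s).
#' @param before_window_s Length of the pre-injection reference window (s),
#'   taken immediately before `injection_s`. Default 300.
#' @param windows_min Matrix-like list of post-injection windows in minutes,
#'   as a two-column matrix `cbind(start, end)`. Default the five consecutive
#'   windows 10-15 ... 30-35 min.
#' @param threshold_frac Change threshold fraction. Default 0.30.
#' @param recording_end_s End of each unit's recording (scalar or per-unit);
#'   default `Inf` (full coverage).
#' @return List with `distributions` (one `change_distribution` per window),
#'   `table` (windows x bins counts), `chisq` (list `statistic`, `df`,
#'   `p_value`; `NA` when degenerate).
#' @export
window_dynamics <- function(trains, injection_s, before_window_s = 300,
                            windows_min = cbind(c(10, 15, 20, 25, 30),
                                                c(15, 20, 25, 30, 35)),
                            threshold_frac = 0.30,
                            recording_end_s = Inf) {
  stopifnot(is.list(trains), injection_s > before_window_s)
  n_units <- length(trains)
  ends <- rep_len(recording_end_s, n_units)
  before <- vapply(trains, rate_in_window,
                   numeric(1), window = c(injection_s - before_window_s,
                                          injection_s))
  labs <- sprintf("%g-%g min", windows_min[, 1], windows_min[, 2])
  dists <- vector("list", nrow(windows_min))
  for (w in seq_len(nrow(windows_min))) {
    win <- injection_s + windows_min[w, ] * 60
    covered <- ends >= win[2]
    after <- rep(NA_real_, n_units)
    after[covered] <- vapply(trains[covered], rate_in_window,
                             numeric(1), window = win)
    bef <- ifelse(covered, before, 0)   # uncovered units drop to excluded
    dists[[w]] <- change_distribution(bef, ifelse(is.na(after), 0, after),
                                      threshold_frac, window_label = labs[w])
  }
  tab <- t(vapply(dists, function(d)
    c(increase = d$n_increase, decrease = d$n_decrease,
      no_change = d$n_no_change), numeric(3)))
  rownames(tab) <- labs
  chisq <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  keep <- colSums(tab) > 0
  if (sum(keep) >= 2 && all(rowSums(tab) > 0)) {
    ct <- suppressWarnings(stats::chisq.test(tab[, keep], correct = FALSE))
    chisq <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                  p_value = unname(ct$p.value))
  } else if (sum(keep) == 1 && all(rowSums(tab) > 0)) {
    # every window puts all units in the same bin: perfectly homogeneous
    chisq <- list(statistic = 0, df = (nrow(tab) - 1) * 2, p_value = 1)
  }
  list(distributions = dists, table = tab, chisq = chisq)
}

#' Chi-squared comparison of treatment vs control change distributions
#'
#' Pearson chi-squared on the 2 x 3 contingency table of
#' (increase, decrease, no change) counts, without continuity correction;
#' with three bins the test has 2 degrees of freedom.
#'
#' @param dist_treat,dist_ctrl [change_distribution()] objects computed at
#'   the same threshold.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
chi2_vs_control <- function(dist_treat, dist_ctrl) {
  stopifnot(inherits(dist_treat, "change_distribution"),
            inherits(dist_ctrl, "change_distribution"))
  if (!isTRUE(all.equal(dist_treat$threshold_frac, dist_ctrl$threshold_frac)))
    stop("distributions use different thresholds")
  tab <- rbind(
    treatment = c(dist_treat$n_increase, dist_treat$n_decrease,
                  dist_treat$n_no_change),
    control = c(dist_ctrl$n_increase, dist_ctrl$n_decrease,
                dist_ctrl$n_no_change))
  colnames(tab) <- c("increase", "decrease", "no_change")
  if (any(rowSums(tab) == 0)) stop("both distributions must contain units")
  if (identical(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))) {
    return(list(statistic = 0, df = 2, p_value = 1, table = tab))
  }
  # bins empty in both groups have zero expected count and contribute
  # nothing; they are dropped from the sum but the test keeps its design
  # df of (3 - 1) x (2 - 1) = 2
  keep <- colSums(tab) > 0
  ct <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE],
                                           correct = FALSE))
  stat <- unname(ct$statistic)
  list(statistic = stat, df = 2,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       table = tab)
}

#' Deterministic post/pre rate-ratio composition for change recovery
#'
#' Allocates `n` units into five true-change categories — strong increase
#' (detected at both the 30% and 10% thresholds), mild increase (detected at
#' 10% only), strong decrease, mild decrease, and no change — by largest
#' remainder, so that the binned fractions at both thresholds equal the
#' requested values exactly up to integer rounding. Each unit's true
#' post/pre ratio is then drawn uniformly within its category band, keeping a
#' margin from both thresholds so that rate-estimation noise rarely flips a
#' bin.
#'
#' @param n Number of units. Default 47.
#' @param frac_inc30,frac_dec30 Target increase/decrease fractions at the 30%
#'   threshold. Defaults 0.51 and 0.29.
#' @param frac_inc10,frac_dec10 Target fractions at the 10% threshold
#'   (supersets of the 30% bins). Defaults 0.56 and 0.36.
#' @return Data frame with `category` and true `ratio` per unit.
#' @export
change_ratio_composition <- function(n = 47, frac_inc30 = 0.51,
                                     frac_dec30 = 0.29, frac_inc10 = 0.56,
                                     frac_dec10 = 0.36) {
  stopifnot(frac_inc10 >= frac_inc30, frac_dec10 >= frac_dec30,
            frac_inc10 + frac_dec10 <= 1)
  fr <- c(strong_inc = frac_inc30, mild_inc = frac_inc10 - frac_inc30,
          strong_dec = frac_dec30, mild_dec = frac_dec10 - frac_dec30)
  fr <- c(fr, no_change = 1 - sum(fr))
  raw <- fr * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  bands <- list(strong_inc = c(1.45, 2.2), mild_inc = c(1.17, 1.23),
                strong_dec = c(0.35, 0.60), mild_dec = c(0.77, 0.83),
                no_change = c(0.96, 1.04))
  cat_names <- rep(names(cnt), cnt)
  ratio <- vapply(cat_names, function(cn)
    stats::runif(1, bands[[cn]][1], bands[[cn]][2]), numeric(1))
  data.frame(category = cat_names, ratio = unname(ratio),
             row.names = NULL)
}
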