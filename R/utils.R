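#' One-dimensional binary erosion
#'
#' Erodes a logical vector with a flat structuring element: a sample stays
#' `TRUE` only if every sample in the centred window of length `len` is
#' `TRUE`. Samples whose window extends past either end are eroded (the
#' vector is conceptually padded with `FALSE`).
#'
#' @param x Logical vector.
#' @param len Structuring-element length in samples (positive integer).
#' @return Logical vector of the same length.
#' @export
erode1d <- function(x, len) {
  stopifnot(is.logical(x), len >= 1, len == round(len))
  if (len == 1) return(x)
  n <- length(x)
  lo <- (len - 1L) %/% 2L          # samples to the left of centre
  hi <- len - 1L - lo
  pad <- c(rep(FALSE, lo), x, rep(FALSE, hi))
  cs <- cumsum(c(0L, as.integer(pad)))
  (cs[seq_len(n) + len] - cs[seq_len(n)]) == len
}

#' One-dimensional binary dilation
#'
#' Dilates a logical vector with a flat structuring element: a sample becomes
#' `TRUE` if any sample in the centred window of length `len` is `TRUE`.
#'
#' @inheritParams erode1d
#' @return Logical vector of the same length.
#' @export
dilate1d <- function(x, len) {
  stopifnot(is.logical(x), len >= 1, len == round(len))
  if (len == 1) return(x)
  n <- length(x)
  lo <- (len - 1L) %/% 2L
  hi <- len - 1L - lo
  pad <- c(rep(FALSE, lo), x, rep(FALSE, hi))
  cs <- cumsum(c(0L, as.integer(pad)))
  (cs[seq_len(n) + len] - cs[seq_len(n)]) > 0L
}

# Runs of TRUE as a two-column matrix of (start, end) sample indices.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Full width at half maximum of a sampled curve
#'
#' The response duration metric: the width of the curve around its extremum at
#' half of the extremum level, with crossings located by linear interpolation
#' between samples. The half-maximum level is referenced to zero, so the input
#' is expected to be a baseline-corrected response (percent signal change).
#' When the curve never falls below the half level on one side, the crossing
#' is taken at the corresponding end of the sampling grid.
#'
#' @param t Sample times (s), strictly increasing.
#' @param y Response values at `t`.
#' @return List with `fwhm_s`, `peak_t`, `peak_value`, and the two crossing
#'   times `t_left`, `t_right`.
#' @export
fwhm <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2, all(diff(t) > 0))
  ipk <- which.max(abs(y))
  pk <- y[ipk]
  if (pk == 0) return(list(fwhm_s = 0, peak_t = t[ipk], peak_value = 0,
                           t_left = t[ipk], t_right = t[ipk]))
  s <- sign(pk)
  yy <- s * y                       # work on a positive-peaked curve
  half <- yy[ipk] / 2
  t_left <- t[1]
  for (i in seq(ipk, 2L)) {
    if (yy[i - 1] < half && yy[i] >= half) {
      t_left <- t[i - 1] + (half - yy[i - 1]) / (yy[i] - yy[i - 1]) *
        (t[i] - t[i - 1])
      break
    }
  }
  n <- length(t)
  t_right <- t[n]
  if (ipk < n) for (i in seq(ipk, n - 1L)) {
    if (yy[i] >= half && yy[i + 1] < half) {
      t_right <- t[i] + (yy[i] - half) / (yy[i] - yy[i + 1]) *
        (t[i + 1] - t[i])
      break
    }
  }
  list(fwhm_s = t_right - t_left, peak_t = t[ipk], peak_value = pk,
       t_left = t_left, t_right = t_right)
}

# Sub-generator seed: derive a distinct 31-bit seed from a master seed and a
# stream index, so each dataset draws from its own seeded generator.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483629) + 1L
}
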