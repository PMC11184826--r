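#' Normalized autocorrelation
#'
#' Biased-estimator autocorrelation normalized by the lag-0 value, so
#' `acf[1] == 1` (lag 0). The mean is removed internally. A constant
#' (zero-variance) input returns 1 at lag 0 and 0 at all other lags rather
#' than NaN, so a degenerate channel contributes nothing to the combined
#' periodicity estimate.
#'
#' @param x numeric vector.
#' @param max_lag maximum lag in samples; must be `< length(x)`.
#' @return Numeric vector of length `max_lag + 1`, lags `0..max_lag`.
#' @export
autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (max_lag >= n) stop("autocorrelation: max_lag must be < length(x)")
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x)))
    return(c(1, numeric(max_lag)))
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE, type = "correlation")$acf)
}

#' Multiparametric autocorrelation of the derived signal pair
#'
#' Element-wise mean of the normalized autocorrelations of the gyration and
#' jerk channels. The arithmetic mean (rather than a sum) keeps the combined
#' curve on the same scale regardless of how many channels contribute.
#'
#' @param sig a [derived_signals()] object.
#' @param max_lag maximum lag in samples.
#' @param use_jerk if `FALSE`, use the gyration channel only (ablation mode).
#' @return Numeric vector of length `max_lag + 1`.
#' @export
multiparametric_acf <- function(sig, max_lag, use_jerk = TRUE) {
  stopifnot(inherits(sig, "derived_signals"))
  a_om <- autocorrelation(sig$omega, max_lag)
  if (!use_jerk) return(a_om)
  a_jk <- autocorrelation(sig$jerk, max_lag)
  (a_om + a_jk) / 2
}

#' Lag of the first prominent autocorrelation peak in a physiological band
#'
#' Scans lags corresponding to `band` (seconds) and returns the first local
#' maximum whose height and topographic prominence both reach `prominence`
#' times the maximum autocorrelation value in the band. Requiring positive
#' height matters: a negative local maximum (e.g. from intra-stride event
#' spacings) cannot indicate a period. If no peak qualifies, the band's
#' global argmax is returned as a fallback.
#'
#' @param acf numeric vector of autocorrelation values at lags `0..max_lag`.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2, lag search band in seconds
#'   (default `c(0.4, 4)`: covers fast healthy cadence through severely slow
#'   pathological gait while excluding step — half-stride — periodicity).
#' @param prominence relative height/prominence threshold (default 0.1).
#' @return Lag in samples.
#' @export
first_peak_lag <- function(acf, fs, band = c(0.4, 4), prominence = 0.1) {
  lo <- max(2L, round(band[1] * fs))
  hi <- min(length(acf) - 2L, round(band[2] * fs))
  if (hi < lo) stop("first_peak_lag: band is empty at this sampling rate")
  vals <- acf[(lo:hi) + 1L]          # acf[k+1] is lag k
  amax <- max(vals)
  thr <- prominence * amax
  for (k in lo:hi) {
    v <- acf[k + 1L]
    if (v > acf[k] && v >= acf[k + 2L] && v >= thr) {
      if (peak_prominence(acf, k + 1L, lo + 1L, hi + 1L) >= thr) return(k)
    }
  }
  lo - 1L + which.max(vals)
}

# topographic prominence of a local maximum at position p (1-based into a),
# restricted to the index range [lo, hi]
peak_prominence <- function(a, p, lo, hi) {
  v <- a[p]
  left <- a[lo:p]; right <- a[p:hi]
  lhigher <- which(left > v)
  lmin <- if (length(lhigher)) min(left[max(lhigher):length(left)]) else min(left)
  rhigher <- which(right > v)
  rmin <- if (length(rhigher)) min(right[1:min(rhigher)]) else min(right)
  v - max(lmin, rmin)
}

#' Estimate the average stride duration from both feet
#'
#' Runs the multiparametric autocorrelation on each foot, locates the first
#' prominent peak per foot, and keeps the shorter of the two estimates to
#' avoid overestimating the stride period. The estimate is a single scalar
#' per walk.
#'
#' @param left,right [derived_signals()] for the two feet.
#' @param band lag search band in seconds, see [first_peak_lag()].
#' @param prominence relative peak threshold.
#' @param use_jerk if `FALSE`, gyration-only ablation mode.
#' @return Object of class `stride_period_estimate`: list with `lag_left`,
#'   `lag_right` (samples), `L` (seconds, `min(lags)/fs`), and the two
#'   autocorrelation curves for diagnostics.
#' @export
estimate_stride_duration <- function(left, right, band = c(0.4, 4),
                                     prominence = 0.1, use_jerk = TRUE) {
  stopifnot(inherits(left, "derived_signals"),
            inherits(right, "derived_signals"))
  fs <- left$fs
  max_lag <- min(round(band[2] * fs) + 2L, left$n - 1L, right$n - 1L)
  acf_l <- multiparametric_acf(left, max_lag, use_jerk = use_jerk)
  acf_r <- multiparametric_acf(right, max_lag, use_jerk = use_jerk)
  lag_l <- first_peak_lag(acf_l, fs, band, prominence)
  lag_r <- first_peak_lag(acf_r, fs, band, prominence)
  structure(list(lag_left = lag_l, lag_right = lag_r,
                 L = min(lag_l, lag_r) / fs, fs = fs,
                 acf_left = acf_l, acf_right = acf_r),
            class = "stride_period_estimate")
}

#' @export
print.stride_period_estimate <- function(x, ...) {
  cat(sprintf(
    "Stride period estimate: L = %.3f s (left lag %d, right lag %d samples at %g Hz)\n",
    x$L, x$lag_left, x$lag_right, x$fs))
  invisible(x)
}
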