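#' Construct an IMU recording
#'
#' Container for one foot's inertial signals: gravity-free acceleration and
#' angular velocity, three axes each, sampled uniformly.
#'
#' @param free_acc numeric matrix, n x 3, gravity-free acceleration (m/s^2),
#'   columns x, y, z.
#' @param gyro numeric matrix, n x 3, angular velocity (deg/s), columns x, y, z.
#' @param foot `"left"` or `"right"`.
#' @param fs sampling rate in Hz.
#' @param t optional sample timestamps in seconds; defaults to `(0:(n-1))/fs`.
#'
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `free_acc`, `gyro`, `foot`, `fs`, `n`. Missing samples (gaps) are
#'   represented as `NA` rows until repaired by [interpolate_gaps()].
#' @export
imu_recording <- function(free_acc, gyro, foot = c("left", "right"), fs = 100,
                          t = NULL) {
  foot <- match.arg(foot)
  free_acc <- as.matrix(free_acc)
  gyro <- as.matrix(gyro)
  n <- nrow(free_acc)
  if (n < 2L) stop("imu_recording: need at least 2 samples")
  if (nrow(gyro) != n) stop("imu_recording: free_acc and gyro lengths differ")
  if (ncol(free_acc) != 3L || ncol(gyro) != 3L)
    stop("imu_recording: channels must have 3 axes")
  if (!is.numeric(fs) || fs <= 0) stop("imu_recording: fs must be positive")
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) stop("imu_recording: t length mismatch")
  dimnames(free_acc) <- dimnames(gyro) <- list(NULL, c("x", "y", "z"))
  structure(list(t = as.numeric(t), free_acc = free_acc, gyro = gyro,
                 foot = foot, fs = fs, n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  gaps <- sum(!stats::complete.cases(cbind(x$free_acc, x$gyro)))
  cat(sprintf("IMU recording (%s foot): %d samples at %g Hz (%.2f s)%s\n",
              x$foot, x$n, x$fs, x$n / x$fs,
              if (gaps) sprintf(", %d samples missing", gaps) else ""))
  invisible(x)
}

#' Read a per-foot IMU CSV export
#'
#' Expects a header row with a sample counter column (`PacketCounter`, or a
#' time column `t`/`Time` in seconds) and six channel columns
#' `freeAccX`, `freeAccY`, `freeAccZ` (m/s^2, gravity-free) and
#' `gyrX`, `gyrY`, `gyrZ` (deg/s). Magnetometer or other extra columns are
#' ignored. Rows missing from the counter sequence are inserted as `NA`
#' samples so that [interpolate_gaps()] can repair them.
#'
#' @param path path to a CSV file.
#' @param foot `"left"` or `"right"`.
#' @param fs sampling rate in Hz (default 100).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, foot = c("left", "right"), fs = 100) {
  foot <- match.arg(foot)
  df <- utils::read.csv(path, check.names = FALSE)
  chan <- c("freeAccX", "freeAccY", "freeAccZ", "gyrX", "gyrY", "gyrZ")
  missing_cols <- setdiff(chan, names(df))
  if (length(missing_cols))
    stop(sprintf("read_imu_csv: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if ("PacketCounter" %in% names(df)) {
    ctr <- as.numeric(df$PacketCounter)
  } else if ("t" %in% names(df) || "Time" %in% names(df)) {
    tt <- if ("t" %in% names(df)) df$t else df$Time
    ctr <- round(as.numeric(tt) * fs)
  } else {
    stop("read_imu_csv: missing required column(s): PacketCounter (or t/Time)")
  }
  if (any(diff(ctr) <= 0))
    stop("read_imu_csv: sample counter is not strictly increasing")
  # expand to a uniform grid, leaving NA rows where counts are missing
  full <- seq(ctr[1], ctr[length(ctr)])
  idx <- match(full, ctr)
  acc <- as.matrix(df[idx, c("freeAccX", "freeAccY", "freeAccZ")])
  gyr <- as.matrix(df[idx, c("gyrX", "gyrY", "gyrZ")])
  imu_recording(acc, gyr, foot = foot, fs = fs,
                t = (full - full[1]) / fs)
}

#' Repair gaps in an IMU recording by quadratic interpolation
#'
#' Every run of missing samples no longer than `max_gap_s` seconds is filled
#' per channel by a quadratic polynomial fitted through the nearest valid
#' neighbours (up to three on each side). A longer gap invalidates the
#' recording, mirroring the logistical exclusion applied to trials whose
#' sensor stopped recording for more than half a second.
#'
#' @param rec an [imu_recording()].
#' @param max_gap_s longest repairable gap, seconds (default 0.5).
#' @return The recording with all gaps filled. Gap-free input is returned
#'   unchanged.
#' @export
interpolate_gaps <- function(rec, max_gap_s = 0.5) {
  stopifnot(inherits(rec, "imu_recording"))
  chans <- cbind(rec$free_acc, rec$gyro)
  bad <- !stats::complete.cases(chans)
  if (!any(bad)) return(rec)
  runs <- rle(bad)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap_runs <- which(runs$values)
  max_len <- max(runs$lengths[gap_runs])
  if (max_len / rec$fs > max_gap_s)
    stop(sprintf(
      "interpolate_gaps: recording invalid: gap of %.2f s exceeds %.2f s",
      max_len / rec$fs, max_gap_s))
  if (bad[1L] || bad[rec$n])
    stop("interpolate_gaps: recording invalid: gap at recording boundary")
  for (g in gap_runs) {
    lo <- starts[g]; hi <- ends[g]
    nb <- c(max(1L, lo - 3L):(lo - 1L), (hi + 1L):min(rec$n, hi + 3L))
    nb <- nb[!bad[nb]]
    for (j in seq_len(ncol(chans))) {
      y <- chans[nb, j]
      x <- rec$t[nb]
      deg <- min(2L, length(nb) - 1L)
      fit <- stats::lm(y ~ stats::poly(x, deg, raw = TRUE))
      chans[lo:hi, j] <- stats::predict(fit,
        newdata = data.frame(x = rec$t[lo:hi]))
    }
  }
  rec$free_acc <- chans[, 1:3, drop = FALSE]
  rec$gyro <- chans[, 4:6, drop = FALSE]
  colnames(rec$free_acc) <- colnames(rec$gyro) <- c("x", "y", "z")
  rec
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase), with odd-reflection padding at both ends to suppress edge
#' transients. Zero-phase application avoids introducing lag between the
#' gyration and jerk signals and against gold-standard timestamps; note that
#' the effective magnitude order doubles (the squared frequency response).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param cutoff cut-off frequency, Hz (default 14).
#' @param order filter order (default 8).
#' @return Filtered vector, same length as `x`. DC gain is 1.
#' @export
lowpass_filter <- function(x, fs, cutoff = 14, order = 8) {
  n <- length(x)
  if (n <= 3L * order)
    stop("lowpass_filter: sequence too short for the requested order")
  if (cutoff >= fs / 2)
    stop("lowpass_filter: cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2))
  np <- min(n - 1L, 300L)
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- as.numeric(signal::filter(bf, c(pre, x, post)))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Low-pass filter all channels of a recording
#'
#' @param rec an [imu_recording()] (gap-free).
#' @inheritParams lowpass_filter
#' @return The recording with every acceleration and gyro channel filtered.
#' @export
filter_recording <- function(rec, cutoff = 14, order = 8) {
  stopifnot(inherits(rec, "imu_recording"))
  rec$free_acc <- apply(rec$free_acc, 2, lowpass_filter,
                        fs = rec$fs, cutoff = cutoff, order = order)
  rec$gyro <- apply(rec$gyro, 2, lowpass_filter,
                    fs = rec$fs, cutoff = cutoff, order = order)
  colnames(rec$free_acc) <- colnames(rec$gyro) <- c("x", "y", "z")
  rec
}

#' Construct the derived signal pair (sagittal gyration, jerk norm)
#'
#' @param omega numeric vector, sagittal-plane angular velocity (deg/s).
#' @param jerk numeric vector, jerk norm (m/s^3), non-negative.
#' @param fs sampling rate, Hz.
#' @param foot optional side label.
#' @return Object of class `derived_signals` with elements `omega`, `jerk`,
#'   `fs`, `n`, `foot`.
#' @export
derived_signals <- function(omega, jerk, fs, foot = NULL) {
  if (length(omega) != length(jerk))
    stop("derived_signals: omega and jerk lengths differ")
  if (any(jerk < 0)) stop("derived_signals: jerk must be non-negative")
  structure(list(omega = as.numeric(omega), jerk = as.numeric(jerk),
                 fs = fs, n = length(omega), foot = foot),
            class = "derived_signals")
}

#' @export
print.derived_signals <- function(x, ...) {
  cat(sprintf("Derived gait signals%s: %d samples at %g Hz (%.2f s)\n",
              if (!is.null(x$foot)) paste0(" (", x$foot, " foot)") else "",
              x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' Derive the two signals of interest from a recording
#'
#' Computes the jerk norm — the Euclidean norm of the time-derivative of the
#' three gravity-free acceleration channels — and copies the sagittal-plane
#' gyration (gyro y axis). Differentiation uses central differences in the
#' interior (second-order accurate, no lag) and one-sided differences at the
#' boundaries.
#'
#' @param rec a gap-free, filtered [imu_recording()].
#' @return A [derived_signals()] object.
#' @export
derive_signals <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (anyNA(rec$free_acc) || anyNA(rec$gyro))
    stop("derive_signals: recording has unrepaired gaps")
  d <- apply(rec$free_acc, 2, finite_diff, fs = rec$fs)
  jerk <- sqrt(rowSums(d^2))
  derived_signals(omega = rec$gyro[, "y"], jerk = jerk,
                  fs = rec$fs, foot = rec$foot)
}

# central differences interior, one-sided forward/backward at the ends
finite_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}

#' Preprocess a raw recording into derived signals
#'
#' Convenience wrapper: gap repair, zero-phase low-pass filtering, and
#' derivation of the (gyration, jerk-norm) pair.
#'
#' @param rec an [imu_recording()].
#' @param cutoff,order Butterworth filter settings (defaults 14 Hz, order 8).
#' @param max_gap_s longest repairable gap in seconds.
#' @return A [derived_signals()] object.
#' @export
preprocess_recording <- function(rec, cutoff = 14, order = 8, max_gap_s = 0.5) {
  rec <- interpolate_gaps(rec, max_gap_s = max_gap_s)
  rec <- filter_recording(rec, cutoff = cutoff, order = order)
  sig <- derive_signals(rec)
  # differentiation of measured acceleration can leave slight negative
  # numerical noise after norm; jerk is a norm, so it is >= 0 by construction
  sig
}
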