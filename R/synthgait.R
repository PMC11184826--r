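#' Parameters for the synthetic gait generator
#'
#' Defaults emulate a healthy 10-m straight walk recorded by foot-worn IMUs
#' at 100 Hz: mean stride time 1.1 s (comfortable healthy cadence at
#' ~1.1 m/s), 9 strides, swing occupying 40% of the stride, 5% stride-time
#' variability and noise at 10% of signal amplitude. Pathology is emulated
#' through amplitude attenuation of the heel-strike jerk burst
#' (`hs_jerk_atten`), raised variability, and left/right asymmetry.
#'
#' @param n_strides strides per foot (>= 2).
#' @param stride_s mean stride time, seconds.
#' @param stride_cv fractional SD of the per-stride duration.
#' @param fs sampling rate, Hz.
#' @param swing_frac swing fraction of the stride (0 < swing_frac < 1).
#' @param asym right/left stride-time ratio (1 = symmetric).
#' @param hs_jerk_atten multiplier in `[0, 1]` on the heel-strike jerk burst
#'   (0 removes it entirely — the equino-varus-foot-like degradation).
#' @param noise_sd additive white-noise SD as a fraction of each channel's
#'   peak amplitude; noise is low-passed at 14 Hz like the real pipeline's
#'   signals.
#' @param lead_s quiet lead-in/lead-out, seconds (walk initiation and
#'   termination off the instrumented area).
#' @param amp_jitter if `TRUE` (default), per-stride burst amplitudes are
#'   jittered by +/- 15-20% (physiological stride-to-stride variability);
#'   `FALSE` makes every stride's morphology identical.
#' @param seed RNG seed; the walk is a deterministic function of the
#'   parameters.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_strides = 9, stride_s = 1.1, stride_cv = 0.05,
                         fs = 100, swing_frac = 0.4, asym = 1,
                         hs_jerk_atten = 1, noise_sd = 0.1,
                         lead_s = 1, amp_jitter = TRUE, seed = 1) {
  if (n_strides < 2) stop("synth_params: n_strides must be >= 2")
  if (stride_s <= 0 || fs <= 0) stop("synth_params: stride_s and fs must be positive")
  if (swing_frac <= 0 || swing_frac >= 1)
    stop("synth_params: swing_frac must lie in (0, 1)")
  if (hs_jerk_atten < 0 || hs_jerk_atten > 1)
    stop("synth_params: hs_jerk_atten must lie in [0, 1]")
  structure(list(n_strides = n_strides, stride_s = stride_s,
                 stride_cv = stride_cv, fs = fs, swing_frac = swing_frac,
                 asym = asym, hs_jerk_atten = hs_jerk_atten,
                 noise_sd = noise_sd, lead_s = lead_s,
                 amp_jitter = amp_jitter, seed = seed),
            class = "synth_params")
}

# morphology constants: amplitudes (deg/s and m/s^3) and burst widths (s).
# Swing gyration peak ~+350 deg/s with negative lobes around TO and HS, a
# small heel-off dip late in stance; jerk bursts at FF/HO/TO/HS with the
# heel-strike impact dominant and foot-flat stance quiet.
.synth_morph <- list(
  omega_swing = 350, omega_to = -90, omega_hs = -120, omega_ho = -45,
  jerk_ff = 60, jerk_ho = 80, jerk_to = 180, jerk_hs = 250,
  w_to = 0.012, w_hs = 0.022, w_ho = 0.015, w_ff = 0.015)

gauss_bump <- function(n, centre, sd, amp) {
  amp * exp(-0.5 * ((seq_len(n) - centre) / sd)^2)
}

#' Synthesize one stride
#'
#' One stride of the (gyration, jerk) pair with exact event offsets. The
#' stride starts just after the previous heel-strike has settled: foot-flat
#' (FF) early, heel-off (HO) late in stance, toe-off (TO) at
#' `(1 - swing_frac)/2` of the stride so that the swing phase — and its
#' dominant positive gyration lobe — is centred, heel-strike (HS) at
#' `TO + swing_frac`.
#'
#' @param params a [synth_params()].
#' @param dur_s stride duration, seconds (default `params$stride_s`).
#' @param jitter if `TRUE`, burst amplitudes are jittered (+/- 15-20%) using
#'   the current RNG state; `FALSE` (default) is fully deterministic.
#' @return List with `omega`, `jerk` (length `round(dur_s * fs)`), the
#'   1-based event offsets `ff`, `ho`, `to`, `hs`, and `n`.
#' @export
synth_stride <- function(params = synth_params(), dur_s = params$stride_s,
                         jitter = FALSE) {
  stopifnot(inherits(params, "synth_params"))
  fs <- params$fs
  n <- round(dur_s * fs)
  sw <- params$swing_frac
  to <- round(n * (0.5 - sw / 2)) + 1L
  hs <- to + round(n * sw)
  ff <- max(2L, round(0.10 * n) + 1L)
  ho <- round(0.20 * n) + 1L
  mid <- (to + hs) / 2
  mo <- .synth_morph
  jit <- function(lo, hi) if (jitter) stats::runif(1, lo, hi) else 1
  omega <- gauss_bump(n, mid, 0.13 * n, mo$omega_swing * jit(0.85, 1.15)) +
    gauss_bump(n, to, 0.035 * n, mo$omega_to * jit(0.85, 1.15)) +
    gauss_bump(n, hs, 0.035 * n, mo$omega_hs * jit(0.85, 1.15)) +
    gauss_bump(n, ho, 0.05 * n, mo$omega_ho * jit(0.85, 1.15))
  jerk <- gauss_bump(n, ff, mo$w_ff * fs, mo$jerk_ff * jit(0.8, 1.2)) +
    gauss_bump(n, ho, mo$w_ho * fs, mo$jerk_ho * jit(0.8, 1.2)) +
    gauss_bump(n, to, mo$w_to * fs, mo$jerk_to * jit(0.8, 1.2)) +
    gauss_bump(n, hs, mo$w_hs * fs,
               mo$jerk_hs * params$hs_jerk_atten * jit(0.8, 1.2))
  list(omega = omega, jerk = jerk, ff = ff, ho = ho, to = to, hs = hs, n = n)
}

#' Synthesize a two-foot walk with ground-truth events
#'
#' Concatenates strides with per-stride durations drawn from a normal
#' distribution truncated at three SDs (mean `stride_s`, SD
#' `stride_cv * stride_s`; the right foot's mean is scaled by `asym` and its
#' first stride is phase-shifted by half a stride), adds quiet lead-in and
#' lead-out segments, then additive white noise followed by the pipeline's
#' own 14 Hz zero-phase low-pass so the synthetic signals share the real
#' preprocessing bandwidth. Ground-truth toe-off and heel-strike times are
#' emitted as an instrumented-walkway-style gold list (FC and IC).
#'
#' @param params a [synth_params()].
#' @return Object of class `synthetic_walk`: list with `left`, `right`
#'   ([derived_signals()]), `truth` (a [gold_event_list()]), per-foot
#'   stride-start indices (`left_starts`, `right_starts`) and `params`.
#' @export
synth_walk <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  fs <- params$fs
  lead <- round(params$lead_s * fs)
  draw_durs <- function(mean_s) {
    sd_s <- params$stride_cv * mean_s
    d <- stats::rnorm(params$n_strides, mean_s, sd_s)
    pmin(pmax(d, mean_s - 3 * sd_s), mean_s + 3 * sd_s)
  }
  build_foot <- function(foot, mean_s, offset) {
    durs <- draw_durs(mean_s)
    omega <- numeric(lead + offset)
    jerk <- numeric(lead + offset)
    starts <- integer(0)
    ev <- list()
    for (d in durs) {
      st <- synth_stride(params, dur_s = d, jitter = params$amp_jitter)
      starts <- c(starts, length(omega) + 1L)
      base <- length(omega)
      ev[[length(ev) + 1L]] <- c(to = base + st$to, hs = base + st$hs)
      omega <- c(omega, st$omega)
      jerk <- c(jerk, st$jerk)
    }
    omega <- c(omega, numeric(lead))
    jerk <- c(jerk, numeric(lead))
    list(omega = omega, jerk = jerk, starts = starts,
         events = do.call(rbind, ev), foot = foot)
  }
  lf <- build_foot("left", params$stride_s, 0L)
  rf <- build_foot("right", params$stride_s * params$asym,
                   round(params$stride_s * fs / 2))
  n <- max(length(lf$omega), length(rf$omega))
  pad <- function(x) c(x, numeric(n - length(x)))
  finish <- function(f) {
    mo <- .synth_morph
    om <- pad(f$omega) + stats::rnorm(n, 0, params$noise_sd * mo$omega_swing)
    jk <- pad(f$jerk) + stats::rnorm(n, 0, params$noise_sd * mo$jerk_hs)
    if (params$noise_sd > 0) {
      om <- lowpass_filter(om, fs)
      jk <- lowpass_filter(jk, fs)
    }
    derived_signals(om, pmax(jk, 0), fs = fs, foot = f$foot)
  }
  left <- finish(lf)
  right <- finish(rf)
  truth <- rbind(
    data.frame(type = "FC", foot = "left", time_s = (lf$events[, "to"] - 1) / fs),
    data.frame(type = "IC", foot = "left", time_s = (lf$events[, "hs"] - 1) / fs),
    data.frame(type = "FC", foot = "right", time_s = (rf$events[, "to"] - 1) / fs),
    data.frame(type = "IC", foot = "right", time_s = (rf$events[, "hs"] - 1) / fs))
  structure(list(left = left, right = right,
                 truth = gold_event_list(truth),
                 left_starts = lf$starts, right_starts = rf$starts,
                 params = params),
            class = "synthetic_walk")
}

#' @export
print.synthetic_walk <- function(x, ...) {
  cat(sprintf(
    "Synthetic walk: %d strides/foot, stride %.2f s (cv %.2f), %.1f s at %g Hz\n",
    x$params$n_strides, x$params$stride_s, x$params$stride_cv,
    x$left$n / x$left$fs, x$left$fs))
  invisible(x)
}

#' Render a synthetic walk as raw per-foot IMU CSV files
#'
#' Writes `left.csv` and `right.csv` in the raw-recording dialect consumed
#' by [read_imu_csv()] (`PacketCounter`, `freeAccX/Y/Z`, `gyrX/Y/Z`) plus
#' `gold.csv` with the ground-truth events. The x acceleration channel is
#' the cumulative sum of a signed jerk track (sign alternating between
#' strides, flipped during quiet foot-flat), so that differentiating it in
#' the preprocessing stage recovers the walk's jerk norm; `gyrY` carries the
#' gyration verbatim. The full pipeline including preprocessing can thus be
#' exercised end to end.
#'
#' @param walk a [synth_walk()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
render_raw_csv <- function(walk, dir) {
  stopifnot(inherits(walk, "synthetic_walk"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- walk$left$fs
  write_foot <- function(sig, starts, file) {
    sgn <- rep(1, sig$n)
    flip <- starts[seq_along(starts) %% 2 == 0]
    for (k in seq_along(flip)) {
      from <- flip[k]
      to <- if (k < length(flip)) flip[k + 1] - 1L else sig$n
      sgn[from:to] <- -1
    }
    acc_x <- cumsum(sgn * sig$jerk) / fs
    df <- data.frame(PacketCounter = seq_len(sig$n),
                     freeAccX = acc_x, freeAccY = 0, freeAccZ = 0,
                     gyrX = 0, gyrY = sig$omega, gyrZ = 0)
    utils::write.csv(df, file, row.names = FALSE)
    file
  }
  lf <- write_foot(walk$left, walk$left_starts, file.path(dir, "left.csv"))
  rf <- write_foot(walk$right, walk$right_starts, file.path(dir, "right.csv"))
  gf <- file.path(dir, "gold.csv")
  utils::write.csv(as.data.frame(walk$truth), gf, row.names = FALSE)
  c(left = lf, right = rf, gold = gf)
}
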