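#' Sliding z-normalized correlation of the annotated template against a walk
#'
#' For every window start, the Pearson correlation between each template
#' channel and the corresponding walk window, averaged over the channels
#' (gyration and jerk, or gyration alone). Values lie in `[-1, 1]`;
#' zero-variance windows score 0.
#'
#' @param sig a [derived_signals()] walk.
#' @param template an `annotated_stride` from [annotate_reference()] (or any
#'   list with `omega`/`jerk` vectors of equal length).
#' @param use_jerk if `FALSE`, correlate the gyration channel only.
#' @return Numeric vector of length `n - m + 1`.
#' @export
correlation_profile <- function(sig, template, use_jerk = TRUE) {
  stopifnot(inherits(sig, "derived_signals"))
  m <- length(template$omega)
  if (m > sig$n) stop("correlation_profile: template longer than signal")
  cp <- sliding_cor(sig$omega, template$omega)
  if (use_jerk) cp <- (cp + sliding_cor(sig$jerk, template$jerk)) / 2
  cp
}

# Pearson correlation of template tpl against every length-m window of x
sliding_cor <- function(x, tpl) {
  m <- length(tpl)
  n <- length(x)
  p <- n - m + 1L
  ts <- stats::sd(tpl) * sqrt((m - 1) / m)     # population sd
  if (!is.finite(ts) || ts == 0) return(numeric(p))
  tz <- (tpl - mean(tpl)) / ts
  W <- matrix(0, p, m)
  for (k in seq_len(m)) W[, k] <- x[k:(k + p - 1L)]
  mu <- rowMeans(W)
  sg <- sqrt(pmax(rowMeans(W^2) - mu^2, 0))
  dots <- as.numeric(W %*% tz)                 # sum(w * tz); sum(tz) = 0
  out <- numeric(p)
  ok <- sg > 1e-12 * max(sg, 1)
  out[ok] <- dots[ok] / (m * sg[ok])
  pmin(1, pmax(-1, out))
}

#' Segmentation parameters
#'
#' @param lambda acceptance threshold on the path-length-normalized mDTWd
#'   dissimilarity between template and candidate window (default 0.4, the
#'   value adapted for degraded strides).
#' @param mu tolerated pairwise overlap between accepted stride windows, as
#'   a fraction of the window length (default 0.1).
#' @param len_band fractional window-length band reserved for a multi-length
#'   candidate search (default `c(0.7, 1.3)`; the default detector tries the
#'   template length only and lets DTW elasticity absorb length variation).
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(lambda = 0.4, mu = 0.1,
                                len_band = c(0.7, 1.3)) {
  if (!(lambda > 0)) stop("segmentation_params: lambda must be positive")
  if (mu < 0 || mu >= 1) stop("segmentation_params: mu must be in [0, 1)")
  structure(list(lambda = lambda, mu = mu, len_band = len_band),
            class = "segmentation_params")
}

# indices of local maxima (first sample of any plateau), excluding endpoints
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}

#' Detect every stride in a walk by template matching
#'
#' Part four of the pipeline. Candidate window starts are the local maxima
#' of the sliding correlation profile of the annotated template against the
#' walk; each candidate is re-scored by the Itakura-constrained mDTWd
#' between template and candidate window, normalized by the warping-path
#' length. Candidates with dissimilarity at most `lambda` are accepted
#' greedily in ascending dissimilarity, subject to pairwise overlap at most
#' `mu * m` samples; TO and HS are then transferred into every accepted
#' window through its warping path.
#'
#' @param sig a [derived_signals()] walk.
#' @param template an `annotated_stride` from [annotate_reference()].
#' @param params a [segmentation_params()] object.
#' @param slope Itakura maximum slope (default 2).
#' @param use_jerk if `FALSE`, gyration-only ablation mode.
#' @param interval optional analysis interval `c(t0, t1)` in seconds;
#'   only strides whose window starts inside it are considered.
#' @return Object of class `gait_event_list`: list with `events` (data frame
#'   with columns `type`, `foot`, `time_s`, time-sorted), `windows`
#'   (accepted window starts, 1-based), `dissimilarity` (per accepted
#'   window) and `m`. If no candidate is accepted a warning is issued and
#'   the event list is empty.
#' @export
detect_strides <- function(sig, template, params = segmentation_params(),
                           slope = 2, use_jerk = TRUE, interval = NULL) {
  stopifnot(inherits(sig, "derived_signals"),
            inherits(params, "segmentation_params"))
  m <- length(template$omega)
  cp <- correlation_profile(sig, template, use_jerk = use_jerk)
  cand <- local_maxima(cp)
  if (!is.null(interval)) {
    t0 <- interval[1] * sig$fs + 1
    t1 <- interval[2] * sig$fs + 1
    cand <- cand[cand >= t0 & cand + m - 1 <= t1]
  }
  fits <- vector("list", length(cand))
  dvals <- rep(Inf, length(cand))
  for (k in seq_along(cand)) {
    s <- cand[k]
    idx <- s:(s + m - 1L)
    fit <- try(suppressWarnings(
      mdtwd(template$omega, if (use_jerk) template$jerk else NULL,
            sig$omega[idx], if (use_jerk) sig$jerk[idx] else NULL,
            slope = slope)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fits[[k]] <- fit
    dvals[k] <- fit$normalized
  }
  keep <- which(dvals <= params$lambda)
  keep <- keep[order(dvals[keep], cand[keep])]
  accepted <- integer(0)
  for (k in keep) {
    s <- cand[k]
    acc_s <- cand[accepted]
    ov <- pmax(0, pmin(acc_s + m, s + m) - pmax(acc_s, s))
    if (all(ov <= params$mu * m)) accepted <- c(accepted, k)
  }
  if (!length(accepted)) {
    warning("detect_strides: no stride matched the template (empty event list)")
    ev <- data.frame(type = character(0), foot = character(0),
                     time_s = numeric(0))
    return(structure(list(events = ev, windows = integer(0),
                          dissimilarity = numeric(0), m = m),
                     class = "gait_event_list"))
  }
  accepted <- accepted[order(cand[accepted])]
  foot <- if (is.null(sig$foot)) "unknown" else sig$foot
  tmpl_events <- list(events = c(TO = template$to_off, HS = template$hs_off))
  rows <- lapply(accepted, function(k) {
    ann <- transfer_events(fits[[k]]$path, tmpl_events, cand[k], m,
                           distance = dvals[k])
    data.frame(type = c("TO", "HS"), foot = foot,
               time_s = c(ann$to_idx - 1L, ann$hs_idx - 1L) / sig$fs)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, windows = cand[accepted],
                 dissimilarity = dvals[accepted], m = m),
            class = "gait_event_list")
}

#' @export
print.gait_event_list <- function(x, ...) {
  cat(sprintf("Gait events: %d TO, %d HS in %d detected strides\n",
              sum(x$events$type == "TO"), sum(x$events$type == "HS"),
              length(x$windows)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Gathers every tunable constant of the four-stage detector. Defaults are
#' the published operating point; all are exposed so that none is hard-coded.
#'
#' @param cutoff,order zero-phase Butterworth low-pass settings (14 Hz,
#'   order 8).
#' @param max_gap_s longest repairable recording gap, seconds (0.5).
#' @param band autocorrelation lag search band, seconds (`c(0.4, 4)`).
#' @param prominence relative peak height/prominence threshold (0.1).
#' @param lambda,mu segmentation acceptance threshold and overlap fraction
#'   (0.4, 0.1).
#' @param slope Itakura maximum path slope (2).
#' @param tol_frac event-matching tolerance as a fraction of the stride
#'   duration (0.2), used by [evaluate_events()].
#' @param use_jerk `FALSE` switches the whole pipeline to gyration-only
#'   ablation mode.
#' @param interval optional analysis interval `c(t0, t1)` in seconds.
#' @param model a [model_stride()] template; `NULL` loads the packaged one.
#' @return Object of class `gaitseg_config`.
#' @export
gaitseg_config <- function(cutoff = 14, order = 8, max_gap_s = 0.5,
                           band = c(0.4, 4), prominence = 0.1,
                           lambda = 0.4, mu = 0.1, slope = 2,
                           tol_frac = 0.2, use_jerk = TRUE,
                           interval = NULL, model = NULL) {
  structure(list(cutoff = cutoff, order = order, max_gap_s = max_gap_s,
                 band = band, prominence = prominence, lambda = lambda,
                 mu = mu, slope = slope, tol_frac = tol_frac,
                 use_jerk = use_jerk, interval = interval, model = model),
            class = "gaitseg_config")
}

#' Detect gait events in a two-foot walk
#'
#' Runs the full four-stage pipeline on a pair of per-foot recordings:
#' preprocessing (gap repair, zero-phase low-pass, signal derivation), a
#' shared stride-period estimate, then per foot the reference-stride motif
#' search, DTW annotation against the model stride, and template-based
#' segmentation.
#'
#' @param left,right the two feet, each either a raw [imu_recording()] (it
#'   will be preprocessed) or an already-derived [derived_signals()] object.
#' @param config a [gaitseg_config()].
#' @return An object of class `gaitseg`: list with `events` (data frame
#'   `type`, `foot`, `time_s` over both feet, time-sorted), `L` (stride
#'   period estimate object), per-foot diagnostics (`motif`, `template`,
#'   `detection`), the `config` and the matched `call`. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @seealso [evaluate_events()] to score the result against a gold standard.
#' @examples
#' walk <- synth_walk(synth_params(n_strides = 6, seed = 42))
#' fit <- gait_segment(walk$left, walk$right)
#' fit
#' head(as.data.frame(fit))
#' @export
gait_segment <- function(left, right, config = gaitseg_config()) {
  cl <- match.call()
  prep <- function(x, foot) {
    if (inherits(x, "derived_signals")) return(x)
    if (!inherits(x, "imu_recording"))
      stop(sprintf("gait_segment: %s input must be an imu_recording or derived_signals",
                   foot))
    tryCatch(
      preprocess_recording(x, cutoff = config$cutoff, order = config$order,
                           max_gap_s = config$max_gap_s),
      error = function(e) stop(sprintf("gait_segment [preprocess, %s foot]: %s",
                                       foot, conditionMessage(e)), call. = FALSE))
  }
  sig_l <- prep(left, "left")
  sig_r <- prep(right, "right")
  if (is.null(sig_l$foot)) sig_l$foot <- "left"
  if (is.null(sig_r$foot)) sig_r$foot <- "right"
  if (sig_l$fs != sig_r$fs) stop("gait_segment: feet sampled at different rates")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("gait_segment [%s]: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  per <- stage("stride period",
               estimate_stride_duration(sig_l, sig_r, band = config$band,
                                        prominence = config$prominence,
                                        use_jerk = config$use_jerk))
  m <- round(per$L * sig_l$fs)
  model <- if (is.null(config$model)) load_model_stride() else config$model
  one_foot <- function(sig) {
    motif <- stage(paste("reference stride,", sig$foot),
                   select_reference_stride(sig, m, use_jerk = config$use_jerk))
    tmpl <- stage(paste("annotation,", sig$foot),
                  annotate_reference(sig, motif, model = model,
                                     slope = config$slope,
                                     use_jerk = config$use_jerk))
    det <- stage(paste("segmentation,", sig$foot),
                 detect_strides(sig, tmpl,
                                params = segmentation_params(config$lambda,
                                                             config$mu),
                                slope = config$slope,
                                use_jerk = config$use_jerk,
                                interval = config$interval))
    list(motif = motif, template = tmpl, detection = det)
  }
  fl <- one_foot(sig_l)
  fr <- one_foot(sig_r)
  ev <- rbind(fl$detection$events, fr$detection$events)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, L = per, m = m,
                 left = fl, right = fr,
                 signals = list(left = sig_l, right = sig_r),
                 config = config, call = cl),
            class = "gaitseg")
}

#' @rdname gait_segment
#' @param left_rec,right_rec recordings, as in `left`/`right`.
#' @export
run_pipeline <- function(left_rec, right_rec, config = gaitseg_config()) {
  gait_segment(left_rec, right_rec, config)
}

#' @export
print.gaitseg <- function(x, ...) {
  cat("Gait segmentation\n")
  cat(sprintf("  stride period L = %.3f s (window m = %d samples)\n",
              x$L$L, x$m))
  for (ft in c("left", "right")) {
    det <- x[[ft]]$detection
    cat(sprintf("  %s foot: %d strides, %d events\n",
                ft, length(det$windows), nrow(det$events)))
  }
  invisible(x)
}

#' @export
summary.gaitseg <- function(object, ...) {
  ev <- object$events
  out <- list(L = object$L$L, m = object$m,
              n_strides = c(left = length(object$left$detection$windows),
                            right = length(object$right$detection$windows)),
              n_events = table(ev$type, ev$foot),
              dissimilarity = c(object$left$detection$dissimilarity,
                                object$right$detection$dissimilarity))
  class(out) <- "summary.gaitseg"
  out
}

#' @export
print.summary.gaitseg <- function(x, ...) {
  cat(sprintf("Gait segmentation: L = %.3f s, m = %d samples\n", x$L, x$m))
  cat(sprintf("Strides: %d left, %d right\n",
              x$n_strides["left"], x$n_strides["right"]))
  print(x$n_events)
  if (length(x$dissimilarity))
    cat(sprintf("Template dissimilarity: median %.3f, max %.3f\n",
                stats::median(x$dissimilarity), max(x$dissimilarity)))
  invisible(x)
}

#' @export
as.data.frame.gaitseg <- function(x, ...) x$events

#' Plot a gait segmentation
#'
#' Gyration traces per foot with detected toe-off and heel-strike times
#' marked.
#'
#' @param x a `gaitseg` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gaitseg <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ft in c("left", "right")) {
    sig <- x$signals[[ft]]
    tt <- (seq_len(sig$n) - 1) / sig$fs
    plot(tt, sig$omega, type = "l", xlab = "time (s)",
         ylab = expression(omega[y] ~ (deg/s)),
         main = paste(ft, "foot"), ...)
    ev <- x$events[x$events$foot == ft, ]
    graphics::abline(v = ev$time_s[ev$type == "TO"], col = "red", lty = 2)
    graphics::abline(v = ev$time_s[ev$type == "HS"], col = "blue", lty = 3)
    graphics::legend("topright", legend = c("TO", "HS"),
                     col = c("red", "blue"), lty = c(2, 3), bty = "n")
  }
  invisible(x)
}
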