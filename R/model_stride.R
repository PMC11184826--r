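#' Construct a model stride
#'
#' A canonical annotated stride template: one stride of gyration and jerk
#' signals plus sample offsets for the four gait events. Toe-off (TO) and
#' heel-strike (HS) are the events the pipeline transfers to subjects;
#' foot-flat (FF) and heel-off (HO) are indicative only.
#'
#' @param omega,jerk numeric vectors, one stride, equal length.
#' @param fs sampling rate, Hz.
#' @param events named integer vector with elements `FF`, `HO`, `TO`, `HS`:
#'   1-based sample offsets within the stride, strictly increasing.
#' @return Object of class `model_stride`.
#' @export
model_stride <- function(omega, jerk, fs, events) {
  n <- length(omega)
  if (length(jerk) != n) stop("model_stride: omega and jerk lengths differ")
  need <- c("FF", "HO", "TO", "HS")
  if (!all(need %in% names(events)))
    stop("model_stride: events must name FF, HO, TO, HS")
  ev <- as.integer(events[need])
  names(ev) <- need
  if (any(ev < 1L) || any(ev > n))
    stop("model_stride: event offsets outside the stride")
  if (any(diff(ev) <= 0))
    stop("model_stride: event offsets must be strictly increasing (FF < HO < TO < HS)")
  structure(list(omega = as.numeric(omega), jerk = as.numeric(jerk),
                 fs = fs, n = n, events = ev),
            class = "model_stride")
}

#' @export
print.model_stride <- function(x, ...) {
  cat(sprintf("Model stride: %d samples at %g Hz; events [FF %d, HO %d, TO %d, HS %d]\n",
              x$n, x$fs, x$events["FF"], x$events["HO"], x$events["TO"],
              x$events["HS"]))
  invisible(x)
}

#' Load the packaged (or a user-supplied) model stride
#'
#' The packaged template is a synthetic canonical stride produced by
#' [synth_stride()] at default parameters with exact event offsets; it stands
#' in for an annotated healthy-subject stride. A user template can be given
#' as a CSV with columns `t`, `omega`, `jerk` plus a JSON sidecar with fields
#' `fs` and `events` (0-based sample offsets for `FF`, `HO`, `TO`, `HS`).
#'
#' @param csv_path,json_path paths to the CSV/JSON pair; `NULL` (default)
#'   loads the packaged synthetic model stride.
#' @return A [model_stride()].
#' @export
load_model_stride <- function(csv_path = NULL, json_path = NULL) {
  if (is.null(csv_path)) {
    csv_path <- system.file("extdata", "model_stride_synthetic.csv",
                            package = "gaitseg", mustWork = TRUE)
    json_path <- system.file("extdata", "model_stride_synthetic.json",
                             package = "gaitseg", mustWork = TRUE)
  }
  if (is.null(json_path))
    json_path <- sub("\\.csv$", ".json", csv_path)
  df <- utils::read.csv(csv_path)
  if (!all(c("omega", "jerk") %in% names(df)))
    stop("load_model_stride: CSV must have columns omega and jerk")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$events))
    stop("load_model_stride: JSON sidecar must carry fs and events")
  ev <- unlist(meta$events) + 1L   # sidecar stores 0-based offsets
  model_stride(df$omega, df$jerk, fs = meta$fs, events = ev)
}

#' Write a model stride to a CSV/JSON pair
#'
#' Inverse of [load_model_stride()]; round-trips exactly up to numeric
#' printing precision.
#'
#' @param ms a [model_stride()].
#' @param csv_path,json_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_model_stride <- function(ms, csv_path, json_path) {
  stopifnot(inherits(ms, "model_stride"))
  df <- data.frame(t = (seq_len(ms$n) - 1) / ms$fs,
                   omega = ms$omega, jerk = ms$jerk)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(list(fs = ms$fs, events = as.list(ms$events - 1L)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' Resample a model stride to a target length
#'
#' Linear interpolation of both channels to `m` samples; event offsets are
#' rescaled proportionally. Needed because the Itakura parallelogram is
#' defined for series of comparable length, so the model is brought to the
#' reference window's length before alignment.
#'
#' @param ms a [model_stride()].
#' @param m target length in samples.
#' @return A [model_stride()] of length `m`.
#' @export
resample_model_stride <- function(ms, m) {
  stopifnot(inherits(ms, "model_stride"))
  if (m == ms$n) return(ms)
  xo <- seq(0, 1, length.out = ms$n)
  xn <- seq(0, 1, length.out = m)
  ev <- round((ms$events - 1L) * (m - 1) / (ms$n - 1)) + 1L
  # proportional rescaling can collapse adjacent indicative events at very
  # short lengths; nudge them apart to preserve strict ordering
  for (k in 2:length(ev)) if (ev[k] <= ev[k - 1L]) ev[k] <- ev[k - 1L] + 1L
  model_stride(stats::approx(xo, ms$omega, xn)$y,
               pmax(0, stats::approx(xo, ms$jerk, xn)$y),
               fs = ms$fs * m / ms$n, events = ev)
}

#' Circularly shift the model stride to centre its swing peak
#'
#' Shifts the model so that the index of its gyration maximum (the swing-peak
#' landmark) coincides with the gyration maximum of the reference window.
#' Event offsets are shifted by the same amount modulo the stride length.
#' After a circular shift the FF < HO < TO < HS ordering may wrap; ordering
#' of the mandatory TO/HS pair is checked downstream, not silently repaired.
#'
#' @param model a [model_stride()].
#' @param ref_omega gyration signal of the reference window (same length).
#' @return A list with the same structure as a `model_stride` (fields
#'   `omega`, `jerk`, `fs`, `n`, `events`), not revalidated for event
#'   ordering; attribute `"shift"` records the applied circular shift.
#' @export
center_align <- function(model, ref_omega) {
  stopifnot(inherits(model, "model_stride"))
  n <- model$n
  if (length(ref_omega) != n)
    stop("center_align: reference window length differs from the model")
  shift <- (which.max(ref_omega) - which.max(model$omega)) %% n
  idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
  ev <- ((model$events - 1L + shift) %% n) + 1L
  out <- model
  out$omega <- model$omega[idx]
  out$jerk <- model$jerk[idx]
  out$events <- ev
  class(out) <- "model_stride"
  attr(out, "shift") <- as.integer(shift)
  out
}
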