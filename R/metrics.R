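#' Construct or read a gold-standard event list
#'
#' Instrumented-walkway annotations: initial contact (IC, matched against
#' detected heel-strikes) and final contact (FC, matched against detected
#' toe-offs).
#'
#' @param events data frame with columns `type` (`"IC"` or `"FC"`), `foot`
#'   (`"left"`/`"right"`) and `time_s` (seconds).
#' @return Object of class `gold_event_list` (the data frame, time-sorted
#'   per foot).
#' @export
gold_event_list <- function(events) {
  stopifnot(all(c("type", "foot", "time_s") %in% names(events)))
  if (!all(events$type %in% c("IC", "FC")))
    stop("gold_event_list: type must be IC or FC")
  events <- events[order(events$foot, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("gold_event_list", "data.frame"))
}

#' @rdname gold_event_list
#' @param path CSV file with the three columns above.
#' @export
read_gold_csv <- function(path) {
  gold_event_list(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' One-to-one matching of detected and gold-standard events
#'
#' Per foot and per event type (detected TO against gold FC, detected HS
#' against gold IC), admissible pairs are those within `tol_frac` of the
#' stride duration; a greedy pass in ascending absolute time difference
#' (ties broken by the earlier gold event) builds a one-to-one matching, so
#' each event on either side is used at most once and no admissible pair
#' with both endpoints free remains.
#'
#' @param detected a `gait_event_list`, a `gaitseg` fit, or a data frame
#'   with columns `type` (`TO`/`HS`), `foot`, `time_s`.
#' @param gold a [gold_event_list()] (or plain data frame with `IC`/`FC`
#'   types).
#' @param stride_duration stride duration in seconds used for the tolerance.
#' @param tol_frac matching tolerance as a fraction of `stride_duration`
#'   (default 0.2).
#' @return Data frame with one row per matched pair: `foot`, `type`
#'   (detected type), `t_detected`, `t_gold`, `abs_err_ms`.
#' @export
match_events <- function(detected, gold, stride_duration, tol_frac = 0.2) {
  if (!is.numeric(stride_duration) || stride_duration <= 0)
    stop("match_events: stride_duration must be positive")
  det <- as_event_df(detected)
  gld <- as.data.frame(gold)
  tol <- tol_frac * stride_duration
  pair_type <- c(TO = "FC", HS = "IC")
  out <- list()
  for (ft in unique(c(det$foot, gld$foot))) {
    for (ty in c("TO", "HS")) {
      dt <- det$time_s[det$foot == ft & det$type == ty]
      gt <- gld$time_s[gld$foot == ft & gld$type == pair_type[[ty]]]
      if (!length(dt) || !length(gt)) next
      cand <- expand.grid(di = seq_along(dt), gi = seq_along(gt))
      cand$err <- abs(dt[cand$di] - gt[cand$gi])
      cand <- cand[cand$err <= tol, , drop = FALSE]
      cand <- cand[order(cand$err, gt[cand$gi]), , drop = FALSE]
      used_d <- logical(length(dt)); used_g <- logical(length(gt))
      for (r in seq_len(nrow(cand))) {
        di <- cand$di[r]; gi <- cand$gi[r]
        if (used_d[di] || used_g[gi]) next
        used_d[di] <- used_g[gi] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          foot = ft, type = ty, t_detected = dt[di], t_gold = gt[gi],
          abs_err_ms = 1000 * abs(dt[di] - gt[gi]))
      }
    }
  }
  if (!length(out))
    return(data.frame(foot = character(0), type = character(0),
                      t_detected = numeric(0), t_gold = numeric(0),
                      abs_err_ms = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$foot, res$type, res$t_gold), , drop = FALSE]
}

as_event_df <- function(x) {
  if (inherits(x, "gaitseg")) return(x$events)
  if (inherits(x, "gait_event_list")) return(x$events)
  as.data.frame(x)
}

#' F1 score (harmonic mean of recall and precision)
#'
#' @param recall,precision fractions in `[0, 1]`.
#' @return `2 * recall * precision / (recall + precision)`, with the
#'   convention that the score is 0 when both inputs are 0.
#' @examples
#' f1_score(0.997, 0.992)   # 0.9945
#' @export
f1_score <- function(recall, precision) {
  if (any(recall < 0 | recall > 1) || any(precision < 0 | precision > 1))
    stop("f1_score: recall and precision must lie in [0, 1]")
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' Evaluate detected gait events against a gold standard
#'
#' Computes recall (matched gold events over all gold events), precision
#' (matched detections over all detections), the F1 score, and the absolute
#' timing-error distributions for toe-off and heel-strike, in milliseconds,
#' over correctly matched events.
#'
#' @inheritParams match_events
#' @param stride_duration stride duration in seconds for the matching
#'   tolerance; `NULL` (default) estimates it as the mean gold inter-FC
#'   interval per foot, averaged over feet.
#' @return Object of class `gait_eval`: recall, precision, f1, the matched
#'   pairs, `delta_to`/`delta_hs` error vectors (ms) and their summaries
#'   (median, IQR, mean). With an empty gold list, recall is `NA` and a
#'   flag `undefined_recall` is set rather than propagating NaN.
#' @export
evaluate_events <- function(detected, gold, stride_duration = NULL,
                            tol_frac = 0.2) {
  det <- as_event_df(detected)
  gld <- as.data.frame(gold)
  if (is.null(stride_duration)) {
    per_foot <- vapply(unique(gld$foot), function(ft) {
      tt <- sort(gld$time_s[gld$foot == ft & gld$type == "FC"])
      if (length(tt) >= 2) mean(diff(tt)) else NA_real_
    }, numeric(1))
    stride_duration <- mean(per_foot, na.rm = TRUE)
    if (!is.finite(stride_duration))
      stop("evaluate_events: cannot infer stride_duration from the gold list; supply it")
  }
  matched <- match_events(det, gld, stride_duration, tol_frac)
  n_gold <- nrow(gld)
  n_det <- nrow(det)
  n_match <- nrow(matched)
  recall <- if (n_gold == 0) NA_real_ else n_match / n_gold
  precision <- if (n_det == 0) NA_real_ else n_match / n_det
  f1 <- if (is.na(recall) || is.na(precision)) NA_real_
        else f1_score(recall, precision)
  d_to <- matched$abs_err_ms[matched$type == "TO"]
  d_hs <- matched$abs_err_ms[matched$type == "HS"]
  summ <- function(v) {
    if (!length(v)) return(c(median = NA, iqr_lo = NA, iqr_hi = NA, mean = NA))
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    c(median = stats::median(v), iqr_lo = q[1], iqr_hi = q[2], mean = mean(v))
  }
  structure(list(recall = recall, precision = precision, f1 = f1,
                 matched = matched, n_gold = n_gold, n_detected = n_det,
                 delta_to = d_to, delta_hs = d_hs,
                 to_summary = summ(d_to), hs_summary = summ(d_hs),
                 stride_duration = stride_duration, tol_frac = tol_frac,
                 undefined_recall = n_gold == 0),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat("Gait event evaluation\n")
  if (x$undefined_recall) {
    cat("  empty gold standard: recall undefined\n")
  } else {
    cat(sprintf("  recall %.3f, precision %.3f, F1 %.3f (%d/%d gold matched)\n",
                x$recall, x$precision, x$f1, nrow(x$matched), x$n_gold))
  }
  fmt <- function(lbl, s, n) {
    if (is.na(s["median"])) return()
    cat(sprintf("  %s: median %.0f ms (IQR [%.0f-%.0f]), mean %.0f ms over %d events\n",
                lbl, s["median"], s["iqr_lo"], s["iqr_hi"], s["mean"], n))
  }
  fmt("deltaTO", x$to_summary, length(x$delta_to))
  fmt("deltaHS", x$hs_summary, length(x$delta_hs))
  invisible(x)
}
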