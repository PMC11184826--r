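#' Itakura parallelogram feasibility mask
#'
#' Logical matrix marking the cells a warping path may visit when its local
#' slope is bounded between `1/slope` and `slope` (relative to the main
#' diagonal), anchored at both corners — the classical parallelogram global
#' constraint.
#'
#' @param n1,n2 lengths of the two series (rows, columns).
#' @param slope maximum path slope (default 2).
#' @return `n1 x n2` logical matrix, `TRUE` where feasible.
#' @export
itakura_mask <- function(n1, n2, slope = 2) {
  if (!is.finite(slope)) return(matrix(TRUE, n1, n2))
  if (slope <= 1) stop("itakura_mask: slope must exceed 1")
  i <- seq_len(n1) - 1
  # for row i (0-based), feasible j satisfy four corner-anchored line bounds
  smax <- slope * (n2 - 1) / (n1 - 1)
  smin <- (1 / slope) * (n2 - 1) / (n1 - 1)
  lo <- pmax(smin * i, (n2 - 1) - smax * ((n1 - 1) - i))
  hi <- pmin(smax * i, (n2 - 1) - smin * ((n1 - 1) - i))
  mask <- matrix(FALSE, n1, n2)
  for (r in seq_len(n1)) {
    jl <- ceiling(lo[r] - 1e-9); jh <- floor(hi[r] + 1e-9)
    if (jh >= jl) mask[r, (jl:jh) + 1L] <- TRUE
  }
  mask
}

# z-normalize one channel of one series; constant channels become zeros
znorm <- function(x, label = "channel") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning(sprintf("mdtwd: %s has zero variance; set to zeros after normalization",
                    label))
    return(numeric(length(x)))
  }
  (x - mean(x)) / s
}

#' Dependent multivariate dynamic time warping (mDTWd)
#'
#' Aligns two bivariate series — (gyration, jerk) stacked into 2-D points —
#' by a dynamic program minimizing the sum of pointwise Euclidean distances
#' along the warping path, with steps (1,0), (0,1), (1,1) and an optional
#' Itakura slope constraint. Each channel is z-normalized per series before
#' stacking ("normalized Euclidean distance with normalized signals");
#' dependence means the two channels are warped jointly, never separately.
#'
#' Ties in the dynamic program are broken deterministically: the diagonal
#' step is preferred, then advancing the first series, then the second.
#'
#' @param a_omega,a_jerk channels of the first series (e.g. the model);
#'   `a_jerk = NULL` gives univariate (gyration-only) alignment.
#' @param b_omega,b_jerk channels of the second series.
#' @param slope Itakura maximum slope; `Inf` disables the constraint.
#' @return List with `distance` (summed cost along the optimal path),
#'   `path` (L x 2 integer matrix of 1-based index pairs, monotone,
#'   boundary-complete), and `normalized` (`distance / nrow(path)`).
#' @export
mdtwd <- function(a_omega, a_jerk, b_omega, b_jerk, slope = 2) {
  n1 <- length(a_omega); n2 <- length(b_omega)
  if (n1 < 2L || n2 < 2L) stop("mdtwd: series must have length >= 2")
  ao <- znorm(a_omega, "series 1 omega")
  bo <- znorm(b_omega, "series 2 omega")
  if (is.null(a_jerk)) {
    local <- sqrt(outer(ao, bo, "-")^2)
  } else {
    aj <- znorm(a_jerk, "series 1 jerk")
    bj <- znorm(b_jerk, "series 2 jerk")
    local <- sqrt(outer(ao, bo, "-")^2 + outer(aj, bj, "-")^2)
  }
  mask <- itakura_mask(n1, n2, slope)
  if (!mask[1, 1] || !mask[n1, n2])
    stop("mdtwd: no Itakura-feasible path exists for these lengths")
  D <- matrix(Inf, n1, n2)
  D[1, 1] <- local[1, 1]
  for (j in 2:n2) if (mask[1, j]) D[1, j] <- D[1, j - 1] + local[1, j]
  for (i in 2:n1) {
    if (mask[i, 1]) D[i, 1] <- D[i - 1, 1] + local[i, 1]
    js <- which(mask[i, ])
    for (j in js[js >= 2L]) {
      best <- min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      if (is.finite(best)) D[i, j] <- best + local[i, j]
    }
  }
  if (!is.finite(D[n1, n2]))
    stop("mdtwd: no Itakura-feasible path exists for these lengths")
  # backtrack; prefer diagonal, then (1,0), then (0,1)
  path <- matrix(NA_integer_, n1 + n2, 2)
  i <- n1; j <- n2; k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L && D[i - 1, j - 1] <= D[i - 1, j] &&
        D[i - 1, j - 1] <= D[i, j - 1]) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && (j == 1L || D[i - 1, j] <= D[i, j - 1])) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  list(distance = D[n1, n2], path = path,
       normalized = D[n1, n2] / nrow(path))
}

#' Transfer model events to a subject window through a warping path
#'
#' The toe-off estimate is the *last* subject sample matched with the model's
#' TO point; the heel-strike estimate is the *first* subject sample matched
#' with the model's HS point.
#'
#' @param path warping path from [mdtwd()] (model indices in column 1,
#'   subject indices in column 2).
#' @param model aligned model stride (list with an `events` element holding
#'   1-based `TO` and `HS` offsets).
#' @param window_start 1-based start of the subject window in walk
#'   coordinates.
#' @param m window length in samples.
#' @param distance mDTWd dissimilarity to record.
#' @return Object of class `annotated_stride`: list with `window`
#'   (`c(start, start + m)`, half-open, walk coordinates), `to_idx`,
#'   `hs_idx` (1-based walk sample indices) and `distance`.
#' @export
transfer_events <- function(path, model, window_start, m, distance = NA_real_) {
  to_off <- model$events[["TO"]]
  hs_off <- model$events[["HS"]]
  jt <- path[path[, 1] == to_off, 2]
  jh <- path[path[, 1] == hs_off, 2]
  if (!length(jt) || !length(jh))
    stop("transfer_events: model event index absent from the warping path")
  to_idx <- window_start - 1L + max(jt)
  hs_idx <- window_start - 1L + min(jh)
  if (to_idx >= hs_idx)
    warning("transfer_events: TO does not precede HS within the window")
  structure(list(window = c(window_start, window_start + m),
                 to_idx = to_idx, hs_idx = hs_idx, distance = distance),
            class = "annotated_stride")
}

#' Annotate the reference stride against the model stride
#'
#' Orchestrates part three of the pipeline: resamples the model stride to
#' the reference window's length, circularly shifts it so both swing peaks
#' coincide, aligns model to reference with [mdtwd()] under the Itakura
#' constraint, and transfers the TO/HS annotations through the warping path.
#'
#' @param sig a [derived_signals()] walk.
#' @param motif a `motif_result` from [select_reference_stride()].
#' @param model a [model_stride()]; `NULL` loads the packaged template.
#' @param slope Itakura maximum slope (default 2).
#' @param use_jerk if `FALSE`, gyration-only alignment.
#' @return An `annotated_stride` carrying, in addition to the event indices,
#'   the reference window's signals and within-window event offsets
#'   (`omega`, `jerk`, `to_off`, `hs_off`) for use as a segmentation
#'   template.
#' @export
annotate_reference <- function(sig, motif, model = NULL, slope = 2,
                               use_jerk = TRUE) {
  stopifnot(inherits(sig, "derived_signals"), inherits(motif, "motif_result"))
  if (is.null(model)) model <- load_model_stride()
  m <- motif$m
  idx <- motif$start:(motif$start + m - 1L)
  ref_om <- sig$omega[idx]
  ref_jk <- sig$jerk[idx]
  mod <- resample_model_stride(model, m)
  mod <- center_align(mod, ref_om)
  fit <- mdtwd(mod$omega, if (use_jerk) mod$jerk else NULL,
               ref_om, if (use_jerk) ref_jk else NULL, slope = slope)
  ann <- transfer_events(fit$path, mod, motif$start, m,
                         distance = fit$normalized)
  ann$omega <- ref_om
  ann$jerk <- ref_jk
  ann$to_off <- ann$to_idx - motif$start + 1L
  ann$hs_off <- ann$hs_idx - motif$start + 1L
  ann$fs <- sig$fs
  ann
}

#' @export
print.annotated_stride <- function(x, ...) {
  cat(sprintf(
    "Annotated stride: window [%d, %d), TO at sample %d, HS at sample %d (mDTWd %.3f)\n",
    x$window[1], x$window[2], x$to_idx, x$hs_idx, x$distance))
  invisible(x)
}
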