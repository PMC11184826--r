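#' Matrix profile (z-normalized Euclidean distance, self-join)
#'
#' For every length-`m` subsequence of `x`, the z-normalized Euclidean
#' distance to its nearest neighbour outside a trivial-match exclusion zone
#' of `m/2` samples. Minima of the profile mark recurring motifs.
#'
#' Computation is exact (all-pairs via blocked cross-products), not an
#' anytime approximation; signals here are short walks, so the quadratic
#' cost is immaterial.
#'
#' @param x numeric vector of length `n >= 2m`.
#' @param m subsequence (window) length in samples, `>= 4`.
#' @param exclusion half-width of the trivial-match exclusion zone
#'   (default `ceiling(m/2)`).
#' @return Numeric vector of length `n - m + 1`; attribute `"nn"` holds the
#'   nearest-neighbour index (1-based window start) of each window.
#' @export
matrix_profile <- function(x, m, exclusion = ceiling(m / 2)) {
  n <- length(x)
  if (m < 4) stop("matrix_profile: window length m must be >= 4")
  if (n < 2 * m)
    stop("matrix_profile: signal too short (need n >= 2m)")
  p <- n - m + 1L
  W <- matrix(0, p, m)
  for (k in seq_len(m)) W[, k] <- x[k:(k + p - 1L)]
  mu <- rowMeans(W)
  sg <- sqrt(pmax(rowMeans(W^2) - mu^2, 0))
  eps <- 1e-12 * max(sg, 1)
  const <- sg <= eps
  mp <- rep(Inf, p)
  nn <- rep(NA_integer_, p)
  block <- 512L
  for (b0 in seq(1L, p, by = block)) {
    rows <- b0:min(b0 + block - 1L, p)
    QT <- W[rows, , drop = FALSE] %*% t(W)      # cross-products
    # squared z-normalized distance via the correlation identity
    denom <- outer(sg[rows], sg)
    num <- QT - m * outer(mu[rows], mu)
    rho <- num / (m * denom)
    d2 <- 2 * m * (1 - rho)
    # degenerate (constant) windows: distance 0 to another constant window,
    # sqrt(m) to a non-constant one (standard convention)
    if (any(const)) {
      cr <- const[rows]
      d2[cr, ] <- m
      d2[, const] <- m
      d2[cr, const] <- 0
    }
    d2[d2 < 0] <- 0
    # exclusion zone |i - j| < exclusion
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      ex <- max(1L, i - exclusion + 1L):min(p, i + exclusion - 1L)
      d2[ri, ex] <- Inf
      j <- which.min(d2[ri, ])
      mp[i] <- sqrt(d2[ri, j])
      nn[i] <- j
    }
  }
  attr(mp, "nn") <- nn
  mp
}

#' Annotation vector favouring a centred swing phase
#'
#' For each window start `i`, sums `omega[k]/omega_max + jerk[k]/jerk_max`
#' over the central third of the window, `k` from `i + floor(m/3)` to
#' `i + floor(2m/3)` inclusive (0-based offsets). `omega_max` is the global
#' maximum of `|omega|` over the walk, `jerk_max` the global maximum of the
#' (non-negative) jerk. Gyration values are used signed, so a window whose
#' centre holds the large positive swing lobe — and strong jerk activity —
#' scores highest. The raw vector is then min-max rescaled to `[0, 1]`; if
#' it is flat (zero range) it is replaced by all ones (no correction).
#'
#' @param omega,jerk numeric vectors of equal length.
#' @param m window length in samples.
#' @param use_jerk if `FALSE`, the jerk term is dropped (gyration-only
#'   ablation mode).
#' @return Numeric vector of length `n - m + 1` in `[0, 1]`; attribute
#'   `"raw"` holds the unscaled sums.
#' @export
annotation_vector <- function(omega, jerk, m, use_jerk = TRUE) {
  n <- length(omega)
  if (length(jerk) != n) stop("annotation_vector: length mismatch")
  p <- n - m + 1L
  if (p < 1L) stop("annotation_vector: window longer than signal")
  om_max <- max(abs(omega))
  jk_max <- max(jerk)
  if (om_max == 0 && (!use_jerk || jk_max == 0))
    stop("annotation_vector: degenerate input (all-zero signals)")
  score <- if (om_max > 0) omega / om_max else numeric(n)
  if (use_jerk && jk_max > 0) score <- score + jerk / jk_max
  k0 <- floor(m / 3)
  k1 <- floor(2 * m / 3)
  cs <- c(0, cumsum(score))
  i <- seq_len(p)                    # window start, 1-based
  raw <- cs[i + k1 + 1L] - cs[i + k0]  # inclusive sum over offsets k0..k1
  rng <- range(raw)
  av <- if (diff(rng) == 0) rep(1, p) else (raw - rng[1]) / diff(rng)
  attr(av, "raw") <- raw
  av
}

#' Corrected matrix profile
#'
#' Combines a matrix profile with an annotation vector using the standard
#' correction rule `cmp = mp + (1 - av) * max(mp)`: windows with low
#' annotation value are pushed up by up to the profile's maximum, so the
#' profile minimum moves to a well-annotated window.
#'
#' @param mp matrix profile (numeric).
#' @param av annotation vector rescaled to `[0, 1]`, same length.
#' @return Numeric vector `cmp`, same length; `cmp >= mp` element-wise.
#' @export
corrected_matrix_profile <- function(mp, av) {
  if (length(mp) != length(av))
    stop("corrected_matrix_profile: length mismatch")
  finite <- is.finite(mp)
  mx <- if (any(finite)) max(mp[finite]) else 0
  mp + (1 - av) * mx
}

#' Select the subject-specific reference stride
#'
#' Composes [matrix_profile()] (on the gyration channel), the
#' [annotation_vector()] (gyration and jerk), and the
#' [corrected_matrix_profile()]; the reference stride is the window starting
#' at the corrected profile's argmin.
#'
#' @param sig a [derived_signals()] object.
#' @param m window length in samples (typically `round(L * fs)` from the
#'   stride-period estimate).
#' @param use_jerk if `FALSE`, gyration-only ablation mode.
#' @return Object of class `motif_result`: list with `m`, `mp`, `av`, `cmp`,
#'   `start` (1-based sample index of the reference window) and `window`
#'   (`c(start, start + m)`, half-open).
#' @export
select_reference_stride <- function(sig, m, use_jerk = TRUE) {
  stopifnot(inherits(sig, "derived_signals"))
  mp <- matrix_profile(sig$omega, m)
  av <- annotation_vector(sig$omega, sig$jerk, m, use_jerk = use_jerk)
  cmp <- corrected_matrix_profile(mp, av)
  start <- which.min(cmp)
  structure(list(m = m, mp = mp, av = av, cmp = cmp, start = start,
                 window = c(start, start + m)),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf(
    "Reference stride: window [%d, %d) (m = %d samples), CMP min = %.3f\n",
    x$start, x$start + x$m, x$m, min(x$cmp)))
  invisible(x)
}
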