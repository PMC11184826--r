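# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately naive and share no code with the package internals.

# z-normalized Euclidean distance between two equal-length vectors
bf_znorm_dist <- function(a, b) {
  zn <- function(v) {
    s <- sqrt(mean(v^2) - mean(v)^2)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  sqrt(sum((zn(a) - zn(b))^2))
}

# all-pairs matrix profile by direct scan
bf_matrix_profile <- function(x, m, exclusion = ceiling(m / 2)) {
  p <- length(x) - m + 1L
  mp <- rep(Inf, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (abs(i - j) < exclusion) next
      d <- bf_znorm_dist(x[i:(i + m - 1L)], x[j:(j + m - 1L)])
      if (d < mp[i]) mp[i] <- d
    }
  }
  mp
}

# direct evaluation of the annotation-vector sum (inclusive bounds,
# floor(m/3)..floor(2m/3) offsets), before any rescaling
bf_annotation_raw <- function(omega, jerk, m) {
  om_max <- max(abs(omega))
  jk_max <- max(jerk)
  p <- length(omega) - m + 1L
  out <- numeric(p)
  for (i in seq_len(p)) {
    s <- 0
    for (k in floor(m / 3):floor(2 * m / 3)) {
      s <- s + omega[i + k] / om_max + jerk[i + k] / jk_max
    }
    out[i] <- s
  }
  out
}

# exhaustive-enumeration DTW on z-normalized stacked channels: minimum over
# every monotone warping path (steps (1,0), (0,1), (1,1)) of the summed
# pointwise Euclidean distance. Exponential; keep inputs tiny (n <= 8).
bf_mdtwd <- function(a_omega, a_jerk, b_omega, b_jerk) {
  zn <- function(v) (v - mean(v)) / sd(v)
  A <- cbind(zn(a_omega), zn(a_jerk))
  B <- cbind(zn(b_omega), zn(b_jerk))
  n1 <- nrow(A); n2 <- nrow(B)
  cost <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  rec <- function(i, j) {
    if (i == n1 && j == n2) return(0)
    best <- Inf
    if (i < n1 && j < n2) best <- min(best, rec(i + 1, j + 1) + cost(i + 1, j + 1))
    if (i < n1) best <- min(best, rec(i + 1, j) + cost(i + 1, j))
    if (j < n2) best <- min(best, rec(i, j + 1) + cost(i, j + 1))
    best
  }
  cost(1, 1) + rec(1, 1)
}

# write a minimal raw IMU CSV for IO tests
write_imu_fixture <- function(path, counter, acc_x = NULL, gyr_y = NULL,
                              drop = NULL) {
  n <- length(counter)
  df <- data.frame(PacketCounter = counter,
                   freeAccX = if (is.null(acc_x)) seq_len(n) else acc_x,
                   freeAccY = 0, freeAccZ = 0,
                   gyrX = 0,
                   gyrY = if (is.null(gyr_y)) seq_len(n) * 2 else gyr_y,
                   gyrZ = 0)
  if (!is.null(drop)) df[[drop]] <- NULL
  write.csv(df, path, row.names = FALSE)
  path
}
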