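test_that("matrix profile is near zero for exact repeats and degenerate windows", {
  m <- 40
  x <- rep(sin(2 * pi * (0:(m - 1)) / m), 10)
  mp <- matrix_profile(x, m)
  expect_lt(max(mp), 1e-6)

  # all z-normalized windows of a strict ramp are identical
  mp2 <- matrix_profile(seq(0, 5, length.out = 200), 20)
  expect_lt(max(mp2), 1e-6)

  expect_error(matrix_profile(rnorm(50), 30), "too short")
  expect_error(matrix_profile(rnorm(50), 3), ">= 4")
})

test_that("matrix profile equals the brute-force all-pairs oracle", {
  set.seed(7)
  for (m in c(8, 16)) {
    x <- rnorm(150)
    mp <- matrix_profile(x, m)
    expect_equal(as.numeric(mp), bf_matrix_profile(x, m), tolerance = 1e-6)
  }
})

test_that("two embedded motifs are found amid noise", {
  set.seed(42)
  pat <- sin(2 * pi * (0:29) / 30) * 3
  x <- c(rnorm(40), pat, rnorm(60), pat, rnorm(40))
  mp <- matrix_profile(x, 30)
  starts <- c(41, 131)
  expect_lte(min(abs(which.min(mp) - starts)), 2)
  expect_equal(as.numeric(mp), bf_matrix_profile(x, 30), tolerance = 1e-6)
})

test_that("annotation vector matches direct evaluation of its defining sum", {
  # saturated signals: every term is 1 + 1, inclusive offsets floor(m/3)..floor(2m/3)
  m <- 6
  av <- annotation_vector(rep(5, 30), rep(2, 30), m)
  expect_equal(as.numeric(attr(av, "raw")), rep(6, 25))
  expect_equal(as.numeric(av), rep(1, 25))   # flat raw vector => no correction

  set.seed(9)
  om <- rnorm(120); jk <- abs(rnorm(120))
  for (m in c(9, 20)) {
    av <- annotation_vector(om, jk, m)
    expect_equal(as.numeric(attr(av, "raw")), bf_annotation_raw(om, jk, m),
                 tolerance = 1e-12)
    expect_true(all(av >= 0 & av <= 1))
  }
})

test_that("annotation vector centres an isolated swing bump", {
  n <- 200; centre <- 100; m <- 60
  om <- exp(-0.5 * ((seq_len(n) - centre) / 5)^2)
  jk <- rep(0.1, n)
  av <- annotation_vector(om, jk, m)
  raw <- attr(av, "raw")
  expect_lte(abs(which.max(raw) - (centre - m / 2)), 2)

  # all-negative gyration: terms are <= 0 but finite, no error
  av2 <- annotation_vector(-om, jk, m)
  expect_true(all(is.finite(av2)))

  expect_error(annotation_vector(numeric(50), numeric(50), 10), "degenerate")
})

test_that("the corrected matrix profile applies the standard correction rule", {
  set.seed(2)
  mp <- abs(rnorm(50))
  expect_equal(corrected_matrix_profile(mp, rep(1, 50)), mp)
  expect_equal(corrected_matrix_profile(mp, rep(0, 50)), mp + max(mp))
  expect_error(corrected_matrix_profile(mp, rep(1, 49)), "mismatch")

  # a well-annotated, slightly worse window overtakes a poorly annotated minimum
  mp2 <- c(0.5, 0.2, 0.6, 0.25, 0.7)
  av2 <- c(0.5, 0, 1, 1, 0.5)
  cmp <- corrected_matrix_profile(mp2, av2)
  expect_equal(cmp, mp2 + (1 - av2) * 0.7)
  expect_equal(which.min(cmp), 4L)

  expect_true(all(cmp >= mp2))
})

test_that("reference stride selection lands on a true stride, invariantly to scaling", {
  walk <- synth_walk(synth_params(seed = 5))
  sig <- walk$left
  est <- estimate_stride_duration(walk$left, walk$right)
  m <- round(est$L * sig$fs)
  res <- select_reference_stride(sig, m)
  expect_equal(which.min(res$cmp), res$start)
  expect_true(res$start >= 1 && res$start <= sig$n - m + 1)
  # start close to a true stride start, swing peak inside the central third
  expect_lte(min(abs(walk$left_starts - res$start)), 0.15 * m)
  win <- sig$omega[res$start:(res$start + m - 1)]
  expect_gte(which.max(win), floor(m / 3))
  expect_lte(which.max(win), ceiling(2 * m / 3))

  sig2 <- derived_signals(2.5 * sig$omega - 10, sig$jerk, sig$fs)
  res2 <- select_reference_stride(sig2, m)
  expect_equal(res2$start, res$start)

  expect_error(select_reference_stride(sig, sig$n), "too short")
})

test_that("a minimal two-stride signal selects one of the two strides", {
  st <- synth_stride(synth_params())
  om <- c(st$omega, st$omega)
  jk <- c(st$jerk, st$jerk)
  res <- select_reference_stride(derived_signals(om, jk, 100), st$n)
  expect_lte(min(abs(res$start - c(1, st$n + 1))), 2)
})
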