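test_that("correlation profile hits 1 on exact tiles and -1 on negations", {
  st <- synth_stride(synth_params())
  tmpl <- list(omega = st$omega, jerk = st$jerk)
  walk <- derived_signals(rep(st$omega, 5), rep(st$jerk, 5), 100)
  cp <- correlation_profile(walk, tmpl)
  tile_starts <- st$n * (0:4) + 1
  expect_true(all(abs(cp[tile_starts] - 1) < 1e-6))

  neg <- derived_signals(c(st$omega, -st$omega), c(st$jerk, max(st$jerk) - st$jerk), 100)
  cp2 <- correlation_profile(neg, tmpl)
  expect_equal(cp2[st$n + 1], -1, tolerance = 1e-6)

  expect_error(correlation_profile(derived_signals(rnorm(50), abs(rnorm(50)), 100),
                                   list(omega = rnorm(60), jerk = abs(rnorm(60)))),
               "longer")
})

test_that("correlation profile of white noise stays below 0.5", {
  st <- synth_stride(synth_params())
  tmpl <- list(omega = st$omega, jerk = st$jerk)
  for (s in 1:3) {
    set.seed(s)
    walk <- derived_signals(rnorm(1e4), abs(rnorm(1e4)), 100)
    expect_lt(max(correlation_profile(walk, tmpl)), 0.5)
  }
})

test_that("identical noiseless strides are all detected exactly", {
  p <- synth_params(n_strides = 10, stride_cv = 0, noise_sd = 0,
                    amp_jitter = FALSE, seed = 1)
  walk <- synth_walk(p)
  fit <- gait_segment(walk$left, walk$right)
  for (ft in c("left", "right")) {
    det <- fit[[ft]]$detection
    expect_equal(length(det$windows), 10L)
    tr <- walk$truth[walk$truth$foot == ft, ]
    for (ty in c("TO", "HS")) {
      gt <- sort(tr$time_s[tr$type == if (ty == "TO") "FC" else "IC"])
      dt <- sort(det$events$time_s[det$events$type == ty])
      expect_equal(length(dt), 10L)
      expect_lte(max(abs(dt - gt)), 1 / walk$left$fs + 1e-9)
    }
  }
})

test_that("a pure-noise walk yields an empty event list with a warning", {
  walk <- synth_walk(synth_params(seed = 2))
  est <- estimate_stride_duration(walk$left, walk$right)
  mres <- select_reference_stride(walk$left, round(est$L * walk$left$fs))
  tmpl <- annotate_reference(walk$left, mres)
  set.seed(11)
  noise <- derived_signals(rnorm(3000), abs(rnorm(3000)), 100, foot = "left")
  expect_warning(out <- detect_strides(noise, tmpl), "no stride")
  expect_equal(nrow(out$events), 0L)
})

test_that("overlapping candidates are resolved greedily by dissimilarity", {
  # a template whose tiling is half-period ambiguous: every half-shift matches
  # perfectly, so acceptance must space windows by the overlap rule
  m <- 60
  base <- sin(2 * pi * (0:(m - 1)) / (m / 2))
  tmpl <- list(omega = base, jerk = abs(base) + 0.1, to_off = 20L, hs_off = 40L)
  walk <- derived_signals(rep(base, 6), rep(abs(base) + 0.1, 6), 100, "left")
  out <- detect_strides(walk, tmpl)
  w <- sort(out$windows)
  if (length(w) > 1)
    expect_true(all(diff(w) >= (1 - 0.1) * m))
  expect_true(all(out$dissimilarity <= 0.4))
})

test_that("accepted windows respect the overlap and dissimilarity bounds", {
  walk <- synth_walk(synth_params(seed = 9, stride_cv = 0.15))
  fit <- suppressWarnings(gait_segment(walk$left, walk$right))
  for (ft in c("left", "right")) {
    det <- fit[[ft]]$detection
    w <- sort(det$windows)
    m <- det$m
    if (length(w) > 1) {
      ov <- pmax(0, w[-length(w)] + m - w[-1])
      expect_true(all(ov <= 0.1 * m + 1e-9))
    }
    expect_true(all(det$dissimilarity <= 0.4))
    # each detected stride carries exactly one TO and one HS
    expect_equal(sum(det$events$type == "TO"), length(w))
    expect_equal(sum(det$events$type == "HS"), length(w))
  }
})

test_that("detection is deterministic", {
  walk <- synth_walk(synth_params(seed = 4))
  f1 <- gait_segment(walk$left, walk$right)
  f2 <- gait_segment(walk$left, walk$right)
  expect_identical(f1$events, f2$events)
})

test_that("mean F1 degrades monotonically with noise (one reversal tolerated)", {
  mean_f1 <- sapply(c(0.05, 0.2, 0.45), function(nz) {
    mean(sapply(1:6, function(s) {
      walk <- synth_walk(synth_params(seed = s, noise_sd = nz, n_strides = 6))
      fit <- suppressWarnings(gait_segment(walk$left, walk$right))
      evl <- suppressWarnings(evaluate_events(fit, walk$truth))
      evl$f1
    }))
  })
  expect_true(sum(diff(mean_f1) > 1e-9) <= 1)
})

test_that("the pipeline reports the failing foot for invalid recordings", {
  walk <- synth_walk(synth_params(seed = 1, n_strides = 4))
  n <- 600
  acc <- matrix(rnorm(3 * n), n, 3)
  acc[100:170, ] <- NA              # 0.7 s gap > 0.5 s limit
  gy <- matrix(rnorm(3 * n), n, 3)
  bad <- imu_recording(acc, gy, "left", fs = 100)
  expect_error(gait_segment(bad, walk$right), "left")
})

test_that("gait_segment methods print, summarise and convert", {
  walk <- synth_walk(synth_params(seed = 6, n_strides = 5))
  fit <- gait_segment(walk$left, walk$right)
  expect_output(print(fit), "stride period")
  expect_output(print(summary(fit)), "Strides")
  df <- as.data.frame(fit)
  expect_true(all(c("type", "foot", "time_s") %in% names(df)))
  expect_false(is.unsorted(df$time_s))
})
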