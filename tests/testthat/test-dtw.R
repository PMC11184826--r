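test_that("model stride fixture loads, validates ordering, and round-trips", {
  ms <- load_model_stride()
  expect_s3_class(ms, "model_stride")
  ev <- ms$events
  expect_true(all(diff(ev[c("FF", "HO", "TO", "HS")]) > 0))

  expect_error(model_stride(rnorm(50), abs(rnorm(50)), 100,
                            c(FF = 5, HO = 10, TO = 40, HS = 20)),
               "increasing")

  d <- withr::local_tempdir()
  csv <- file.path(d, "ms.csv"); js <- file.path(d, "ms.json")
  write_model_stride(ms, csv, js)
  ms2 <- load_model_stride(csv, js)
  expect_equal(ms2$events, ms$events)
  expect_equal(ms2$omega, ms$omega, tolerance = 1e-9)
  expect_equal(ms2$jerk, ms$jerk, tolerance = 1e-9)
})

test_that("center_align shifts the swing peak and is invertible", {
  ms <- load_model_stride()
  ref <- ms$omega
  al <- center_align(ms, ref)
  expect_equal(attr(al, "shift"), 0L)
  expect_equal(al$omega, ms$omega)

  n <- ms$n
  shift_by <- 20L
  ref2 <- ms$omega[((seq_len(n) - 1L - shift_by) %% n) + 1L]
  al2 <- center_align(ms, ref2)
  expect_equal(attr(al2, "shift"), shift_by)
  expect_equal(al2$omega, ref2)
  expect_equal(al2$events[["TO"]],
               ((ms$events[["TO"]] - 1L + shift_by) %% n) + 1L)

  back <- center_align(al2, ms$omega)
  expect_equal(back$omega, ms$omega)
  expect_equal(back$events, ms$events)
})

test_that("mdtwd is zero on identical series with a diagonal path", {
  set.seed(3)
  ao <- rnorm(30); aj <- abs(rnorm(30))
  fit <- mdtwd(ao, aj, ao, aj)
  expect_equal(fit$distance, 0, tolerance = 1e-12)
  expect_equal(fit$path, cbind(a = 1:30, b = 1:30))
  expect_equal(fit$normalized, 0, tolerance = 1e-12)
})

test_that("mdtwd treats the stacked channels symmetrically", {
  set.seed(5)
  ao <- rnorm(20); aj <- rnorm(20)
  bo <- rnorm(20); bj <- rnorm(20)
  f1 <- mdtwd(ao, aj, bo, bj)
  f2 <- mdtwd(aj, ao, bj, bo)    # swap channels consistently in both series
  expect_equal(f1$distance, f2$distance)
  f3 <- mdtwd(bo, bj, ao, aj)    # swap the series
  expect_equal(f1$distance, f3$distance)
})

test_that("a repeated sample is absorbed by a unit warp step", {
  set.seed(8)
  n <- 60
  ao <- cumsum(rnorm(n)); aj <- cumsum(rnorm(n))
  k <- 30
  bo <- ao[c(1:k, k, (k + 1):n)]
  bj <- aj[c(1:k, k, (k + 1):n)]
  fit <- mdtwd(ao, aj, bo, bj, slope = Inf)
  expect_lt(fit$normalized, 0.05)   # z-normalization changes values slightly
  expect_equal(nrow(fit$path), n + 1L)
})

test_that("mdtwd equals the exhaustive-path oracle and the Itakura bound holds", {
  set.seed(21)
  for (rep in 1:5) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    ao <- rnorm(n1); aj <- rnorm(n1)
    bo <- rnorm(n2); bj <- rnorm(n2)
    un <- mdtwd(ao, aj, bo, bj, slope = Inf)
    expect_equal(un$distance, bf_mdtwd(ao, aj, bo, bj), tolerance = 1e-9)
    it <- try(mdtwd(ao, aj, bo, bj, slope = 2), silent = TRUE)
    if (!inherits(it, "try-error"))
      expect_gte(it$distance, un$distance - 1e-9)
  }
  # when the unconstrained optimum is the diagonal, the constrained cost equals it
  set.seed(22)
  ao <- rnorm(8); aj <- rnorm(8)
  expect_equal(mdtwd(ao, aj, ao, aj, slope = 2)$distance,
               mdtwd(ao, aj, ao, aj, slope = Inf)$distance)
})

test_that("constant channels are zeroed with a warning, not an error", {
  set.seed(2)
  ao <- rnorm(20); bo <- rnorm(20)
  expect_warning(fit <- mdtwd(ao, rep(1, 20), bo, abs(rnorm(20))),
                 "zero variance")
  expect_true(is.finite(fit$distance))
})

test_that("transfer_events applies the last-TO / first-HS matching rules", {
  model <- list(events = c(TO = 30, HS = 70))
  # identity path: events map to themselves
  p <- cbind(1:100, 1:100)
  ann <- transfer_events(p, model, window_start = 1L, m = 100)
  expect_equal(ann$to_idx, 30L)
  expect_equal(ann$hs_idx, 70L)

  # repeated matches: TO takes the last subject index, HS the first
  p2 <- rbind(cbind(1:29, 1:29),
              c(30, 58), c(30, 59), c(30, 60),
              cbind(31:69, 61:99),
              c(70, 100), c(70, 101), c(70, 102),
              cbind(71:100, 103:132))
  ann2 <- transfer_events(p2, model, window_start = 1L, m = 132)
  expect_equal(ann2$to_idx, 60L)
  expect_equal(ann2$hs_idx, 100L)

  # window offset shifts both into walk coordinates
  ann3 <- transfer_events(p, model, window_start = 501L, m = 100)
  expect_equal(ann3$to_idx, 530L)
  expect_equal(ann3$hs_idx, 570L)
})

test_that("annotating the model against itself is a fixed point", {
  ms <- load_model_stride()
  al <- center_align(ms, ms$omega)
  fit <- mdtwd(al$omega, al$jerk, ms$omega, ms$jerk)
  ann <- transfer_events(fit$path, al, window_start = 1L, m = ms$n)
  expect_equal(ann$to_idx, ms$events[["TO"]])
  expect_equal(ann$hs_idx, ms$events[["HS"]])
})

test_that("reference-stride annotation recovers true events within 40 ms", {
  for (s in c(2, 6, 13)) {
    walk <- synth_walk(synth_params(seed = s))
    for (ft in c("left", "right")) {
      sig <- walk[[ft]]
      est <- estimate_stride_duration(walk$left, walk$right)
      mres <- select_reference_stride(sig, round(est$L * sig$fs))
      ann <- annotate_reference(sig, mres)
      tr <- walk$truth[walk$truth$foot == ft, ]
      to_err <- min(abs(tr$time_s[tr$type == "FC"] - (ann$to_idx - 1) / sig$fs))
      hs_err <- min(abs(tr$time_s[tr$type == "IC"] - (ann$hs_idx - 1) / sig$fs))
      expect_lt(to_err, 0.040)
      expect_lt(hs_err, 0.040)
    }
  }
})
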