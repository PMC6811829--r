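# Population traces, locomotion epoching, fractional change, E/I analyses.

test_that("population mean and boxcar smoothing behave as an average", {
  n <- 400L
  one <- matrix(0.3, n, 1)
  expect_equal(population_mean(one, 10)$values, rep(0.3, n))
  x <- stats::rnorm(n)
  two <- cbind(x, -x)
  expect_equal(population_mean(two, 10)$values, rep(0, n))
  # white noise: smoothed variance drops by about the window length
  set.seed(8)
  w <- matrix(stats::rnorm(20000), ncol = 1)
  pm <- population_mean(w, frame_rate_hz = 10, window_s = 5)  # 50 frames
  ratio <- stats::var(pm$values[100:19900]) / stats::var(as.vector(w))
  expect_equal(ratio, 1 / 50, tolerance = 0.3)
})

test_that("stationary mask pads running bouts", {
  expect_true(all(stationary_mask(rep(0, 100), 10)))
  sp <- rep(0, 100); sp[41:50] <- 5
  m <- stationary_mask(sp, 10, speed_threshold = 1, pad_s = 1)
  expect_false(any(m[31:60]))
  expect_true(all(m[c(1:30, 61:100)]))
  expect_true(all(stationary_mask(sp, 10, speed_threshold = Inf)))
})

test_that("fractional change matches its defining arithmetic", {
  cfg <- session_config(baseline_duration_s = 10, post_duration_s = 40,
                        rng_seed = 1L)
  tl <- session_timeline(cfg, analysis_offset_s = c(20, 40))
  v <- rep(1, tl$n_frames)
  expect_equal(fractional_change(v, tl), 0)
  v2 <- v; v2[(tl$analysis_window[1] + 1):tl$analysis_window[2]] <- 0.65
  expect_equal(fractional_change(v2, tl), -0.35)
  v3 <- v; v3[(tl$analysis_window[1] + 1):tl$analysis_window[2]] <- 3
  expect_equal(fractional_change(v3, tl), 2)
  # nonpositive baseline flagged
  r <- fractional_change(v * 0, tl)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "baseline")
  # values on running frames cannot influence the result
  stat <- rep(TRUE, tl$n_frames)
  run_idx <- seq(5L, tl$n_frames, by = 7L)
  stat[run_idx] <- FALSE
  v4 <- v2; v4[run_idx] <- stats::rnorm(length(run_idx), 0, 100)
  expect_equal(fractional_change(v4, tl, stationary = stat),
               fractional_change(v2, tl, stationary = stat))
})

test_that("E/I correlation matches Pearson identities and the null", {
  x <- stats::rnorm(500) + 1
  expect_equal(ei_correlation(x, x, c(0L, 500L)), 1)
  expect_equal(ei_correlation(x, -x, c(0L, 500L)), -1)
  set.seed(12)
  a <- stats::rnorm(10000); b <- stats::rnorm(10000)
  expect_lt(abs(ei_correlation(a, b, c(0L, 10000L))), 0.05)
  r <- ei_correlation(rep(1, 100), stats::rnorm(100), c(0L, 100L))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "constant")
  expect_error(ei_correlation(x, x, c(0L, 2L)), "3 frames")
})

test_that("E/I coupling normalizes away baseline differences and common gain", {
  n <- 1000L
  base <- c(0L, 300L)
  exc <- 2 + abs(sin(seq_len(n) / 30))
  inh <- 0.5 * exc   # same shape, different scale
  cp <- ei_coupling(exc, inh, base, 10)
  expect_equal(cp$ratio, rep(1, n), tolerance = 1e-12)
  # excitation doubled after baseline
  exc2 <- exc; exc2[301:n] <- exc[301:n] * 2
  cp2 <- ei_coupling(exc2, exc, base, 10, window_s = 0.1)
  expect_equal(cp2$ratio[400:n], rep(2, n - 399), tolerance = 1e-12)
  # common multiplicative gain on both populations cancels exactly
  g <- 0.6
  cp3 <- ei_coupling(exc * g, inh * g, base, 10)
  expect_equal(cp3$ratio, cp$ratio, tolerance = 1e-12)
})
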