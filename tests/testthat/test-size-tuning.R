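# Evoked amplitudes, tuning curves, DoG fits and the suppression index.

make_log <- function(n_trials, sizes, fr = 10) {
  log <- data.frame(onset_frame = (seq_len(n_trials) - 1L) * 120L,
                    size_deg = rep_len(sizes, n_trials),
                    orientation_deg = 0)
  attr(log, "phase_durations_s") <- c(5, 2, 2, 3)
  log
}

test_that("trial amplitudes are drift-phase maxima with moving flags", {
  log <- make_log(3L, c(10, 20, 30))
  n <- 400L
  dff <- matrix(0, n, 2)
  # a transient peaking at 0.8 inside trial 2's drift window (frames 171:190)
  dff[175:185, 1] <- 0.8 * exp(-abs(-5:5) / 3)
  stat <- rep(TRUE, n); stat[250] <- FALSE   # running during trial 3
  r <- trial_responses(dff, log, 10, stationary = stat)
  expect_equal(nrow(r), 6L)
  expect_equal(r$amplitude[r$roi_id == "2"], rep(0, 3))
  expect_equal(max(r$amplitude), 0.8)
  expect_equal(r$trial[which.max(r$amplitude)], 2L)
  expect_equal(r$moving, rep(c(FALSE, FALSE, TRUE), each = 2))
})

test_that("dog_response implements the closed form of the printed integrals", {
  p <- dog_params(0.3, 1, 0.5, 20, 60)
  expect_equal(dog_response(p, 0), 0.3)
  pe <- dog_params(0.3, 1, 1, 25, 25)
  expect_equal(dog_response(pe, c(0, 10, 47)), rep(0.3, 3))
  # quadrature of the integral form at a reference point
  f <- function(y, cc) exp(-(2 * y / cc)^2)
  p2 <- dog_params(0, 1, 0.5, 20, 60)
  q <- stats::integrate(f, -20, 20, cc = 20, rel.tol = 1e-12)$value -
    0.5 * stats::integrate(f, -20, 20, cc = 60, rel.tol = 1e-12)$value
  expect_equal(dog_response(p2, 40), q, tolerance = 1e-9)
  expect_error(dog_response(p, -1), ">= 0")
})

test_that("the fitted SSI satisfies its defining arithmetic and scaling
          invariance", {
  sizes <- seq(10, 60, 10)
  # calibrate Ki so the true curve has r_max/r_pref = 0.52, then scale so
  # r_pref = 1: SSI must come out as exactly (1 - 0.52)/1 = 0.48
  ratio_at <- function(ki) {
    sm <- capipe:::dog_summary(dog_params(0, 1, ki, 15, 45), sizes)
    sm$r_max / sm$r_pref - 0.52
  }
  ki <- stats::uniroot(ratio_at, c(0.05, 0.4), tol = 1e-10)$root
  p <- dog_params(0, 1, ki, 15, 45)
  sm <- capipe:::dog_summary(p, sizes)
  sc <- 1 / sm$r_pref
  p1 <- dog_params(0, sc, ki * sc, 15, 45)
  sm1 <- capipe:::dog_summary(p1, sizes)
  expect_equal(sm1$r_pref, 1.0, tolerance = 1e-9)
  expect_equal(sm1$r_max, 0.52, tolerance = 1e-9)
  expect_equal(sm1$ssi, 0.48, tolerance = 1e-9)
  # and the full fit applied to that curve reproduces it
  fit <- fit_dog(sizes, dog_response(p1, sizes), seed = 1)
  expect_lt(abs(fit$ssi - 0.48), 0.02)
  expect_equal(fit$ssi, (fit$r_pref - fit$r_max) / fit$r_pref,
               tolerance = 1e-12)
  # multiplicative scaling of the whole curve leaves SSI unchanged
  fit5 <- fit_dog(sizes, 5 * dog_response(p1, sizes), seed = 1)
  expect_lt(abs(fit5$ssi - fit$ssi), 0.02)
})

test_that("fit_dog recovers SSI on noiseless and noisy curves and is
          deterministic", {
  sizes <- seq(10, 60, 10)
  set.seed(31)
  errs_clean <- c(); errs_noisy <- c()
  for (k in 1:25) {
    repeat {
      p <- dog_params(stats::runif(1, 0, 0.2), stats::runif(1, 0.5, 2), 0,
                      stats::runif(1, 5, 40), 1)
      p <- dog_params(p$Rb, p$Ke, p$Ke * stats::runif(1, 0.05, 0.35),
                      p$a, p$a * stats::runif(1, 1.5, 6))
      sm <- capipe:::dog_summary(p, sizes)
      if (sm$ssi_defined && sm$ssi >= 0 && sm$ssi <= 0.8 &&
          sm$r_pref > 0.1) break
    }
    y <- dog_response(p, sizes)
    errs_clean <- c(errs_clean, abs(fit_dog(sizes, y, seed = 1)$ssi - sm$ssi))
    # 10% multiplicative trial noise, 10 trials per size
    ym <- vapply(y, function(m) {
      mean(m * (1 + stats::rnorm(10, 0, 0.1)))
    }, numeric(1))
    errs_noisy <- c(errs_noisy, abs(fit_dog(sizes, ym, seed = 1)$ssi - sm$ssi))
  }
  expect_lte(max(errs_clean), 0.02)
  expect_lte(stats::median(errs_noisy), 0.1)
  # monotonically increasing curve (no surround): SSI ~ 0
  y_mono <- dog_response(dog_params(0.05, 1, 0, 12, 30), sizes)
  expect_lte(abs(fit_dog(sizes, y_mono, seed = 1)$ssi), 0.01)
  # determinism under the seed
  f1 <- fit_dog(sizes, y_mono, seed = 9)
  f2 <- fit_dog(sizes, y_mono, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_error(fit_dog(c(10, 20, 30, 40), c(1, 2, 2, 1)), "5 distinct")
})

test_that("population curves average retained trials only", {
  log <- make_log(12L, seq(10, 60, 10))
  resp <- data.frame(roi_id = rep(c("a", "b"), 12),
                     trial = rep(1:12, each = 2),
                     size_deg = rep(log$size_deg, each = 2),
                     orientation_deg = 0,
                     amplitude = 0.5, moving = FALSE)
  flat <- population_size_curve(resp, log)
  expect_equal(flat$mean_response, rep(0.5, 6))
  expect_equal(flat$roi_id, rep("population", 6))
  # moving trials with wild values do not alter the curve
  resp2 <- resp
  resp2$moving[resp2$trial %in% c(2, 5)] <- TRUE
  resp2$amplitude[resp2$moving] <- 1e6
  expect_equal(population_size_curve(resp2, log)$mean_response, rep(0.5, 6))
  # brute-force per-size grand means
  set.seed(4)
  resp3 <- resp
  resp3$amplitude <- stats::runif(nrow(resp3))
  curve <- population_size_curve(resp3, log)
  for (s in unique(resp3$size_deg)) {
    expect_equal(curve$mean_response[curve$size_deg == s],
                 mean(resp3$amplitude[resp3$size_deg == s]))
  }
})

test_that("preferred-response change follows the pre-epoch preferred size", {
  pre <- data.frame(roi_id = "a", size_deg = seq(10, 60, 10),
                    mean_response = c(0.2, 0.8, 0.6, 0.5, 0.4, 0.3),
                    n_trials = 5)
  expect_equal(preferred_response_change(pre, pre)$fractional_change, 0)
  post <- pre; post$mean_response <- pre$mean_response * 0.4
  pc <- preferred_response_change(pre, post)
  expect_equal(pc$pref_size_deg, 20)
  expect_equal(pc$fractional_change, -0.6)
  post2 <- pre; post2$mean_response <- pre$mean_response * 0.69
  expect_equal(preferred_response_change(pre, post2)$fractional_change,
               -0.31)
})
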