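# Rigid motion correction: shift estimation, registration, cropping.

# Spatial-domain exhaustive-search oracle for the best circular shift.
oracle_shift <- function(frame, reference, max_shift) {
  best <- c(0L, 0L); best_c <- -Inf
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      cc <- stats::cor(as.vector(shift_frame(frame, dy, dx)),
                       as.vector(reference))
      if (cc > best_c) { best_c <- cc; best <- c(dy, dx) }
    }
  }
  best
}

shift_vec <- function(e) c(e[["dy"]], e[["dx"]])

test_that("estimate_shift recovers integer translations and agrees with the
          exhaustive spatial-domain search", {
  set.seed(11)
  ref <- matrix(stats::rnorm(64 * 64), 64)
  expect_equal(shift_vec(estimate_shift(ref, ref, 5)), c(0L, 0L))

  frame <- shift_frame(ref, 3, -2)
  est <- estimate_shift(frame, ref, 5)
  expect_equal(shift_vec(est), c(-3L, 2L))
  expect_equal(shift_vec(est), oracle_shift(frame, ref, 5))

  # a handful of random shifts, cross-checked against the oracle
  for (k in 1:5) {
    s <- sample(-5:5, 2, replace = TRUE)
    fr <- shift_frame(ref, s[1], s[2])
    expect_equal(shift_vec(estimate_shift(fr, ref, 5)),
                 oracle_shift(fr, ref, 5))
  }
})

test_that("degenerate frames are flagged", {
  ref <- matrix(stats::rnorm(32 * 32), 32)
  flat <- matrix(5, 32, 32)
  expect_warning(e <- estimate_shift(flat, ref, 5), "flat")
  expect_equal(shift_vec(e), c(0L, 0L))
  # pure noise vs unrelated reference: within bounds, low confidence
  set.seed(2)
  noise <- matrix(stats::rnorm(32 * 32), 32)
  e2 <- estimate_shift(noise, ref, 4)
  expect_true(all(abs(e2) <= 4))
  expect_false(attr(e2, "confident"))
})

test_that("register_movie undoes known jitter and is idempotent", {
  ses <- imaging_fixture()
  sub <- ses$movie[, , 1:60]
  set.seed(21)
  jit <- cbind(sample(-4:4, 60, TRUE), sample(-4:4, 60, TRUE))
  reg <- register_movie(jitter_movie(sub, jit),
                        reference = apply(sub, c(1, 2), mean),
                        max_shift_px = 6)
  expect_equal(cbind(reg$shifts$dy, reg$shifts$dx), -jit,
               ignore_attr = TRUE)
  # registered movie equals the original on the common (border-cropped)
  # region: circular wrap only affects a border of max|jitter| pixels
  expect_equal(crop_border(reg$movie, 5, 1), crop_border(sub, 5, 1),
               tolerance = 1e-12)
  # idempotence: registering the registered movie gives all-zero shifts
  reg2 <- register_movie(reg$movie, reference = apply(sub, c(1, 2), mean),
                         max_shift_px = 6)
  expect_true(all(reg2$shifts$dy == 0L & reg2$shifts$dx == 0L))
  # determinism
  rega <- register_movie(jitter_movie(sub, jit),
                         reference = apply(sub, c(1, 2), mean),
                         max_shift_px = 6)
  expect_identical(reg$shifts, rega$shifts)
})

test_that("crop_border implements the 20 um rule", {
  m <- array(stats::rnorm(100 * 100 * 3), c(100, 100, 3))
  expect_equal(dim(crop_border(m, 20, 1)), c(60, 60, 3))
  expect_identical(crop_border(m, 0, 1), m)
  expect_error(crop_border(m, 50, 1), "whole field")
})
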