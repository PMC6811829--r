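# Synthetic session generator: schedules, spiking, kinetics, rendering.

test_that("stimulus schedule tiles the session with the fixed phase structure", {
  cfg <- session_config(baseline_duration_s = 6, post_duration_s = 6,
                        rng_seed = 1L)
  # 12 s at 10 Hz holds exactly one 120-frame trial
  log1 <- generate_stimulus_schedule(cfg, sizes = 10)
  expect_equal(nrow(log1), 1L)
  expect_equal(log1$onset_frame, 0L)
  # drift phase spans 2 s = 20 frames
  ph <- attr(log1, "phase_durations_s")
  expect_equal(ph[2L] * cfg$frame_rate_hz, 20)

  cfg2 <- session_config(baseline_duration_s = 360, post_duration_s = 360,
                         rng_seed = 1L)
  log2 <- generate_stimulus_schedule(cfg2, sizes = seq(10, 60, 10),
                                     orientations = c(0, 90))
  expect_equal(diff(log2$onset_frame), rep(120L, nrow(log2) - 1L))
  # each (size, orientation) combination appears in every complete block
  n_comb <- 12L
  first_block <- log2[1:n_comb, ]
  expect_equal(nrow(unique(first_block[c("size_deg", "orientation_deg")])),
               n_comb)
  # determinism
  expect_identical(log2,
                   generate_stimulus_schedule(cfg2, seq(10, 60, 10),
                                              c(0, 90)))
  # too-short session and invalid sizes fail loudly
  expect_error(generate_stimulus_schedule(
    session_config(baseline_duration_s = 3, post_duration_s = 3)),
    "too short")
  expect_error(generate_stimulus_schedule(cfg, sizes = 15), "sizes")
})

test_that("spike generation matches configured rates and drug gain", {
  cell0 <- ground_truth_cell(c(10, 10), 5, baseline_rate_hz = 0)
  cfg <- tiny_config()
  tl <- session_timeline(cfg)
  expect_true(all(generate_spikes(cell0, NULL, tl, cfg) == 0))

  # empirical post/baseline ratio converges to drug_gain (1e5 frames)
  for (g in c(0.65, 3.0)) {
    cfgL <- session_config(baseline_duration_s = 5000,
                           post_duration_s = 5000, drug_gain = g,
                           rng_seed = 3L)
    tlL <- session_timeline(cfgL)
    cell <- ground_truth_cell(c(10, 10), 5, baseline_rate_hz = 1)
    sp <- generate_spikes(cell, NULL, tlL, cfgL, rng_seed = 3L)
    nb <- tlL$injection_frame
    base_rate <- mean(sp[1:nb]) * cfgL$frame_rate_hz
    post_rate <- mean(sp[(nb + 1):length(sp)]) * cfgL$frame_rate_hz
    expect_equal(base_rate, 1, tolerance = 0.05)
    expect_equal(post_rate / base_rate, g, tolerance = 0.05)
  }

  # negative computed rates are clamped with a warning
  neg_dog <- dog_params(Rb = 0, Ke = 0.1, Ki = 2, a = 10, b = 40)
  celln <- ground_truth_cell(c(10, 10), 5, baseline_rate_hz = 0,
                             dog_params = neg_dog)
  cfgS <- session_config(baseline_duration_s = 12, post_duration_s = 12,
                         rng_seed = 1L)
  logS <- generate_stimulus_schedule(cfgS, sizes = 60)
  expect_warning(generate_spikes(celln, logS, session_timeline(cfgS), cfgS),
                 "clamped")
})

test_that("fluorescence kinetics are affine in spikes with unit-peak kernel", {
  cfg <- tiny_config()
  n <- 240L
  expect_equal(spikes_to_fluorescence(integer(n), cfg),
               rep(100, n))
  sp <- integer(n); sp[30L] <- 1L
  f1 <- spikes_to_fluorescence(sp, cfg, amplitude = 20)
  # single spike: peak amplitude = discrete kernel maximum (1) x amplitude
  expect_equal(max(f1) - 100, 20, tolerance = 1e-9)
  # doubling spikes doubles the deflection
  f2 <- spikes_to_fluorescence(sp * 2L, cfg, amplitude = 20)
  expect_equal(f2 - 100, 2 * (f1 - 100), tolerance = 1e-9)
  expect_error(spikes_to_fluorescence(sp, cfg, rise_s = 2, decay_s = 1),
               "rise")
})

test_that("locomotion bouts hit the requested running fraction", {
  cfg <- tiny_config()
  expect_true(all(generate_locomotion(cfg, bout_rate_hz = 0) == 0))
  cfgL <- session_config(baseline_duration_s = 2000, post_duration_s = 2000,
                         rng_seed = 9L)
  sp <- generate_locomotion(cfgL, bout_rate_hz = 0.02, run_fraction = 0.3,
                            rng_seed = 9L)
  expect_true(all(sp >= 0))
  expect_equal(mean(sp > 0), 0.3, tolerance = 0.05)
  expect_identical(sp, generate_locomotion(cfgL, bout_rate_hz = 0.02,
                                           run_fraction = 0.3,
                                           rng_seed = 9L))
})

test_that("rendering is exact by construction without noise", {
  cfg <- tiny_config()
  n <- 120L
  cells <- list(
    ground_truth_cell(c(15, 15), 5),
    ground_truth_cell(c(34, 32), 5.5, cell_type = "pv"))
  traces <- cbind(100 + 10 * sin(seq_len(n) / 5), rep(100, n))

  # no neuropil, no noise: mask mean trace equals the cell trace
  r0 <- render_session(cells, traces, cfg, neuropil_level = 0)
  for (i in 1:2) {
    expect_equal(extract_raw(r0$movie, r0$masks[[i]]), traces[, i],
                 tolerance = 1e-10)
  }

  # zero cell signal: soma pixels carry exactly 0.7 x local neuropil
  rz <- render_session(cells, traces * 0, cfg, neuropil_level = 60)
  idx <- r0$masks[[1]][1, ]
  px_trace <- rz$movie[idx[1], idx[2], ]
  np_trace <- rz$neuropil$trace * rz$neuropil$spatial[idx[1], idx[2]]
  expect_equal(px_trace, 0.7 * np_trace, tolerance = 1e-10)

  # determinism: bit-identical movie under the same seed
  r1 <- render_session(cells, traces, cfg, neuropil_level = 60)
  r2 <- render_session(cells, traces, cfg, neuropil_level = 60)
  expect_identical(r1$movie, r2$movie)
  expect_identical(r1$red, r2$red)

  # overlapping footprints are rejected
  bad <- list(ground_truth_cell(c(15, 15), 5),
              ground_truth_cell(c(17, 16), 5))
  expect_error(render_session(bad, traces, cfg), "overlap")
})

test_that("whole-session simulation is deterministic under a seed", {
  cfg <- tiny_config(noise_sd = 1)
  s1 <- simulate_session(cfg, n_cells = 3L, n_pv = 1L, stimuli = FALSE,
                         baseline_rate_hz = 0.3, render = TRUE)
  s2 <- simulate_session(cfg, n_cells = 3L, n_pv = 1L, stimuli = FALSE,
                         baseline_rate_hz = 0.3, render = TRUE)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$movie, s2$movie)
  expect_identical(s1$locomotion, s2$locomotion)
})
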