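# Synthetic two-photon session generator. Every downstream stage of the
# pipeline is validated against the ground truth this module emits:
# cell masks, spike trains, noiseless fluorescence, the neuropil field and
# its contamination weight, the stimulus log and the locomotion trace.

TREATMENTS <- c("saline", "mk801", "mk801_muscimol")

# Default post-injection rate gains per treatment. Magnitudes mirror the
# in vivo effect sizes the pipeline is meant to resolve: no change under
# saline, ~35% suppression of V1 activity under NMDAR block, partial
# (~14%) suppression when the NMDAR block is combined with ACC
# inactivation.
DEFAULT_DRUG_GAIN <- c(saline = 1.0, mk801 = 0.65, mk801_muscimol = 0.86)

#' Session configuration
#'
#' Global parameters of a synthetic imaging session: geometry, timing,
#' treatment and noise. Defaults follow the experimental design the
#' pipeline targets: ~10 Hz frame rate, a 6-minute baseline recording, a
#' 45-minute post-injection recording, and a true neuropil contamination
#' weight of 0.7.
#'
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param pixel_size_um microns per pixel.
#' @param field_px integer `c(height, width)` of the imaging field.
#' @param baseline_duration_s pre-injection recording duration (s).
#' @param post_duration_s post-injection recording duration (s).
#' @param treatment one of `"saline"`, `"mk801"`, `"mk801_muscimol"`.
#' @param drug_gain multiplicative gain applied to every cell's firing rate
#'   from the injection frame on; defaults by treatment (saline 1, mk801
#'   0.65, mk801_muscimol 0.86).
#' @param neuropil_weight_true weight with which the local neuropil signal
#'   contaminates soma pixels in the rendered movie (in `[0, 1]`).
#' @param noise_sd SD of additive Gaussian pixel noise (a.u.).
#' @param rng_seed integer seed; identical configs and seeds give
#'   bit-identical sessions.
#' @return an object of class `session_config`.
#' @export
session_config <- function(frame_rate_hz = 10, pixel_size_um = 1.0,
                           field_px = c(128L, 128L),
                           baseline_duration_s = 360,
                           post_duration_s = 2700,
                           treatment = "saline",
                           drug_gain = NULL,
                           neuropil_weight_true = 0.7,
                           noise_sd = 2,
                           rng_seed = 1L) {
  treatment <- match.arg(treatment, TREATMENTS)
  if (is.null(drug_gain)) drug_gain <- DEFAULT_DRUG_GAIN[[treatment]]
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(baseline_duration_s, "baseline_duration_s")
  stopifnot_scalar_pos(post_duration_s, "post_duration_s")
  stopifnot_scalar_pos(drug_gain, "drug_gain")
  if (neuropil_weight_true < 0 || neuropil_weight_true > 1) {
    stop("neuropil_weight_true must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cfg <- list(frame_rate_hz = frame_rate_hz, pixel_size_um = pixel_size_um,
              field_px = as.integer(field_px),
              baseline_duration_s = baseline_duration_s,
              post_duration_s = post_duration_s,
              treatment = treatment, drug_gain = drug_gain,
              neuropil_weight_true = neuropil_weight_true,
              noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  structure(cfg, class = "session_config")
}

#' Session timeline: baseline / injection / post epochs
#'
#' All frame intervals are half-open and 0-based: `c(first, end)` covers
#' frames `first, ..., end - 1`. The analysis window defaults to 20-30
#' minutes post injection; if the post epoch is shorter than that, the
#' whole post epoch is used (flagged in `$analysis_window_default`).
#'
#' @param config a [session_config()].
#' @param analysis_offset_s offset of the analysis window from the
#'   injection, in seconds (default `c(1200, 1800)` = 20-30 min).
#' @return object of class `session_timeline` with `baseline_frames`,
#'   `injection_frame`, `post_frames`, `analysis_window`, `n_frames`.
#' @export
session_timeline <- function(config, analysis_offset_s = c(1200, 1800)) {
  fr <- config$frame_rate_hz
  nb <- s_to_frames(config$baseline_duration_s, fr)
  np <- s_to_frames(config$post_duration_s, fr)
  aw <- nb + s_to_frames(analysis_offset_s, fr)
  default_used <- FALSE
  if (aw[1L] >= nb + np) {        # standard window does not fit: whole post
    aw <- c(nb, nb + np)
    default_used <- TRUE
  } else {
    aw[2L] <- min(aw[2L], nb + np)
  }
  structure(list(baseline_frames = c(0L, nb), injection_frame = nb,
                 post_frames = c(nb, nb + np), analysis_window = aw,
                 analysis_window_default = default_used,
                 n_frames = nb + np), class = "session_timeline")
}

#' Ground-truth cell
#'
#' Geometry, identity and generative tuning of one synthetic cell. Somata
#' have radii 4-8 um, boutons at most 1.5 um.
#'
#' @param center_px `c(row, col)` center (1-based pixels).
#' @param radius_um radius in microns.
#' @param kind `"soma"` or `"bouton"`.
#' @param cell_type `"pv"` or `"pyramidal"`.
#' @param baseline_rate_hz spontaneous firing rate (Hz).
#' @param dog_params [dog_params()] giving the evoked firing rate (Hz) as a
#'   function of stimulus size.
#' @param pref_orientation_deg preferred orientation in `[0, 180)`.
#' @param orientation_width_deg tuning width (degrees) of the wrapped
#'   Gaussian orientation tuning.
#' @return object of class `gt_cell`.
#' @export
ground_truth_cell <- function(center_px, radius_um, kind = "soma",
                              cell_type = "pyramidal",
                              baseline_rate_hz = 0.1,
                              dog_params = NULL,
                              pref_orientation_deg = 0,
                              orientation_width_deg = 30) {
  kind <- match.arg(kind, c("soma", "bouton"))
  cell_type <- match.arg(cell_type, c("pv", "pyramidal"))
  if (kind == "soma" && (radius_um < 4 || radius_um > 8)) {
    stop("soma radii must be in [4, 8] um", call. = FALSE)
  }
  if (kind == "bouton" && radius_um > 1.5) {
    stop("bouton radii must be <= 1.5 um", call. = FALSE)
  }
  if (baseline_rate_hz < 0 || !is.finite(baseline_rate_hz)) {
    stop("baseline_rate_hz must be finite and >= 0", call. = FALSE)
  }
  structure(list(center_px = as.numeric(center_px), radius_um = radius_um,
                 kind = kind, cell_type = cell_type,
                 baseline_rate_hz = baseline_rate_hz,
                 dog_params = dog_params,
                 pref_orientation_deg = pref_orientation_deg %% 180,
                 orientation_width_deg = orientation_width_deg),
            class = "gt_cell")
}

#' Generate a stimulus schedule
#'
#' Trials tile the session with the fixed phase structure (stationary 5 s,
#' drifting 2 s, stationary 2 s, 3 s gray-screen gap = 12 s per trial).
#' Each repetition block presents every (size, orientation) combination
#' once in a seeded random order; blocks repeat until the session cannot
#' hold another complete trial.
#'
#' @param config a [session_config()].
#' @param sizes stimulus diameters (degrees), a subset of
#'   `{10, 20, 30, 40, 50, 60}`.
#' @param orientations grating orientations in degrees.
#' @param rng_seed seed for the block shuffles.
#' @param phase_durations_s trial phase durations
#'   `(pre_static, drift, post_static, gap)` in seconds.
#' @return data frame `onset_frame` (0-based), `size_deg`,
#'   `orientation_deg` with the phase durations attached as
#'   `attr(, "phase_durations_s")`.
#' @export
generate_stimulus_schedule <- function(config, sizes = seq(10, 60, 10),
                                       orientations = 0,
                                       rng_seed = config$rng_seed,
                                       phase_durations_s = c(5, 2, 2, 3)) {
  if (!all(sizes %in% seq(10, 60, 10))) {
    stop("sizes must come from {10, 20, 30, 40, 50, 60} degrees",
         call. = FALSE)
  }
  fr <- config$frame_rate_hz
  trial_len <- s_to_frames(sum(phase_durations_s), fr)
  tl <- session_timeline(config)
  n_trials <- tl$n_frames %/% trial_len
  if (n_trials < 1L) {
    stop("session too short to hold a single stimulus trial", call. = FALSE)
  }
  combos <- expand.grid(size_deg = sizes, orientation_deg = orientations)
  sched <- with_seed(rng_seed, {
    blocks <- lapply(seq_len(ceiling(n_trials / nrow(combos))), function(b) {
      combos[sample.int(nrow(combos)), , drop = FALSE]
    })
    do.call(rbind, blocks)[seq_len(n_trials), , drop = FALSE]
  })
  out <- data.frame(onset_frame = (seq_len(n_trials) - 1L) * trial_len,
                    size_deg = sched$size_deg,
                    orientation_deg = sched$orientation_deg)
  attr(out, "phase_durations_s") <- phase_durations_s
  out
}

#' Wrapped-Gaussian orientation tuning factor in [0, 1]
#' @noRd
orientation_factor <- function(theta_deg, pref_deg, width_deg) {
  d <- (theta_deg - pref_deg) %% 180
  d <- pmin(d, 180 - d)
  exp(-(d / width_deg)^2)
}

#' Per-frame firing rate (Hz) of a ground-truth cell
#' @noRd
cell_rate_hz <- function(cell, stim_log, timeline, config) {
  n <- timeline$n_frames
  rate <- rep(cell$baseline_rate_hz, n)
  if (!is.null(stim_log) && nrow(stim_log) > 0L &&
      !is.null(cell$dog_params)) {
    fr <- config$frame_rate_hz
    phases <- attr(stim_log, "phase_durations_s")
    if (is.null(phases)) phases <- c(5, 2, 2, 3)
    d0 <- s_to_frames(phases[[1L]], fr)
    dl <- s_to_frames(phases[[2L]], fr)
    evoked <- dog_response(cell$dog_params, stim_log$size_deg) *
      orientation_factor(stim_log$orientation_deg,
                         cell$pref_orientation_deg,
                         cell$orientation_width_deg)
    for (t in seq_len(nrow(stim_log))) {
      idx <- stim_log$onset_frame[t] + d0 + seq_len(dl)   # 1-based
      idx <- idx[idx <= n]
      rate[idx] <- rate[idx] + evoked[t]
    }
  }
  post <- (timeline$injection_frame + 1L):n
  rate[post] <- rate[post] * config$drug_gain
  if (any(rate < 0)) {
    warning("negative firing rates clamped to 0", call. = FALSE)
    rate[rate < 0] <- 0
  }
  rate
}

#' Generate a frame-binned spike train for one cell
#'
#' Inhomogeneous Poisson spiking: the per-frame rate is the cell's baseline
#' rate, plus its DoG size-tuned, orientation-tuned evoked rate during each
#' trial's drifting phase, multiplied by the treatment's `drug_gain` after
#' the injection frame. An optional per-frame multiplicative
#' `rate_modulation` (mean ~1) models shared slow excitability
#' fluctuations across the population.
#'
#' @param cell a [ground_truth_cell()].
#' @param stim_log stimulus log or `NULL` for a spontaneous (dark) session.
#' @param timeline a [session_timeline()].
#' @param config a [session_config()].
#' @param rng_seed seed for the Poisson draws.
#' @param rate_modulation optional nonnegative per-frame multiplier.
#' @return integer vector of spike counts per frame.
#' @export
generate_spikes <- function(cell, stim_log, timeline, config,
                            rng_seed = config$rng_seed,
                            rate_modulation = NULL) {
  rate <- cell_rate_hz(cell, stim_log, timeline, config)
  if (!is.null(rate_modulation)) {
    stopifnot(length(rate_modulation) == length(rate))
    rate <- rate * pmax(rate_modulation, 0)
  }
  with_seed(rng_seed,
            stats::rpois(length(rate), rate / config$frame_rate_hz))
}

#' GCaMP-like double-exponential kernel, unit peak amplitude
#' @noRd
gcamp_kernel <- function(frame_rate_hz, rise_s = 0.2, decay_s = 1.8) {
  if (rise_s <= 0 || decay_s <= rise_s) {
    stop("kernel needs 0 < rise_s < decay_s", call. = FALSE)
  }
  t_max <- decay_s * 8
  t <- seq(0, t_max, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Convert a spike train to a raw fluorescence trace
#'
#' Convolves the frame-binned spike counts with a difference-of-exponentials
#' indicator kernel (defaults 0.2 s rise, 1.8 s decay, GCaMP6s-like) whose
#' peak is normalized to 1, scales by `amplitude` (fluorescence a.u. per
#' spike) and adds the resting fluorescence `f_rest`. The trace is affine
#' in the spike counts.
#'
#' @param spikes integer spike counts per frame.
#' @param config a [session_config()] (supplies the frame rate).
#' @param rise_s,decay_s kernel time constants (s), `0 < rise < decay`.
#' @param amplitude fluorescence units added at the peak of a single-spike
#'   transient.
#' @param f_rest resting fluorescence, `> 0`.
#' @return numeric fluorescence trace, same length as `spikes`.
#' @export
spikes_to_fluorescence <- function(spikes, config, rise_s = 0.2,
                                   decay_s = 1.8, amplitude = 20,
                                   f_rest = 100) {
  stopifnot_scalar_pos(f_rest, "f_rest")
  k <- gcamp_kernel(config$frame_rate_hz, rise_s, decay_s)
  n <- length(spikes)
  sig <- stats::convolve(as.numeric(spikes), rev(k), type = "open")[seq_len(n)]
  f_rest + amplitude * sig
}

#' Generate a locomotion trace
#'
#' Alternating stationary and running bouts with exponentially distributed
#' durations. `bout_rate_hz` sets how many running bouts occur per second
#' of session and `run_fraction` the expected fraction of time spent
#' running; running speed is a positive bout-specific level plus jitter.
#'
#' @param config a [session_config()].
#' @param bout_rate_hz running bouts per second (0 = never runs).
#' @param run_fraction expected fraction of frames spent running.
#' @param run_speed_cms mean running speed (cm/s).
#' @param rng_seed seed.
#' @return numeric vector, speed in cm/s per frame (0 while stationary).
#' @export
generate_locomotion <- function(config, bout_rate_hz = 0.02,
                                run_fraction = 0.15, run_speed_cms = 8,
                                rng_seed = config$rng_seed) {
  if (bout_rate_hz < 0) stop("bout_rate_hz must be >= 0", call. = FALSE)
  n <- session_timeline(config)$n_frames
  speed <- numeric(n)
  if (bout_rate_hz == 0 || run_fraction <= 0) return(speed)
  fr <- config$frame_rate_hz
  mean_run <- run_fraction / bout_rate_hz            # seconds
  mean_stat <- (1 - run_fraction) / bout_rate_hz
  with_seed(rng_seed, {
    pos <- 0L
    running <- FALSE
    while (pos < n) {
      dur_s <- stats::rexp(1, 1 / (if (running) mean_run else mean_stat))
      len <- max(1L, s_to_frames(dur_s, fr))
      idx <- (pos + 1L):min(pos + len, n)
      if (running) {
        level <- run_speed_cms * stats::runif(1, 0.6, 1.4)
        speed[idx] <- pmax(level + stats::rnorm(length(idx), 0, 1), 0.5)
      }
      pos <- pos + len
      running <- !running
    }
  })
  speed
}

#' Shared multiplicative rate modulation (mean ~1)
#'
#' Band-limited smoothed Gaussian noise scaled to `amplitude` SD around 1
#' and clamped at 0; models population-wide excitability fluctuations that
#' couple the activity of simultaneously recorded cells. Components slower
#' than `highcut_s` are removed: slow shared drift is the neuropil field's
#' job, and within one session it would be indistinguishable from a
#' treatment effect.
#'
#' @param config a [session_config()].
#' @param amplitude SD of the modulation around 1.
#' @param timescale_s smoothing window (s) setting the fast timescale.
#' @param highcut_s window (s) of the slow moving average subtracted to
#'   remove low-frequency content.
#' @param rng_seed seed.
#' @return numeric per-frame multiplier.
#' @export
generate_shared_modulation <- function(config, amplitude = 0.3,
                                       timescale_s = 5, highcut_s = 30,
                                       rng_seed = config$rng_seed) {
  n <- session_timeline(config)$n_frames
  fr <- config$frame_rate_hz
  w <- max(2L, s_to_frames(timescale_s, fr))
  ws <- max(w + 1L, s_to_frames(highcut_s, fr))
  z <- with_seed(rng_seed, stats::rnorm(n + 2L * ws))
  z <- moving_average(z, w)
  z <- z - moving_average(z, ws)
  z <- z[ws + seq_len(n)]
  z <- (z - mean(z)) / stats::sd(z)
  pmax(1 + amplitude * z, 0)
}

#' Pixels of a disc mask around a cell center, clipped to the field
#' @noRd
disc_pixels <- function(center, radius_px, field) {
  r <- ceiling(radius_px)
  rows <- max(1L, floor(center[1L] - r)):min(field[1L], ceiling(center[1L] + r))
  cols <- max(1L, floor(center[2L] - r)):min(field[2L], ceiling(center[2L] + r))
  g <- expand.grid(row = rows, col = cols)
  d <- sqrt((g$row - center[1L])^2 + (g$col - center[2L])^2)
  keep <- d <= radius_px
  list(rc = as.matrix(g[keep, , drop = FALSE]), dist = d[keep])
}

#' Radial intensity profile: annular ("donut") for somata, disc for boutons
#' @noRd
cell_profile <- function(dist, radius_px, kind) {
  if (kind == "soma") {
    exp(-((dist - 0.62 * radius_px) / (0.38 * radius_px))^2)
  } else {
    exp(-(dist / (0.7 * radius_px))^2)
  }
}

#' Smooth positive neuropil spatial map, mean 1
#' @noRd
neuropil_spatial_map <- function(field, sigma_px = 20, amplitude = 0.25,
                                 rng_seed = 1L) {
  if (amplitude == 0) return(matrix(1, field[1L], field[2L]))
  sigma_px <- min(sigma_px, (min(field) - 2) / 7)   # keep brush in-field
  z <- with_seed(rng_seed,
                 matrix(stats::rnorm(prod(field)), field[1L], field[2L]))
  s <- matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(z),
                                                sigma = sigma_px)),
              field[1L], field[2L])
  s <- s / stats::sd(s)
  pmax(1 + amplitude * s, 0.2)
}

#' Slow positive neuropil temporal trace
#' @noRd
neuropil_temporal_trace <- function(n_frames, frame_rate_hz, level = 60,
                                    rng_seed = 1L) {
  w <- max(2L, s_to_frames(20, frame_rate_hz))
  z <- with_seed(rng_seed, stats::rnorm(n_frames + 2L * w))
  z <- moving_average(z, w)[w + seq_len(n_frames)]
  z <- (z - mean(z)) / stats::sd(z)
  drift <- sin(seq(0, 3 * pi, length.out = n_frames))
  pmax(level * (1 + 0.15 * z + 0.08 * drift), 0)
}

#' Render a synthetic movie from cells and their fluorescence traces
#'
#' Background pixels carry the shared neuropil field
#' (spatial map x slow temporal trace). Each cell pixel carries the cell's
#' fluorescence scaled by a radial profile (annular for somata - nuclear
#' exclusion - and disc-shaped for boutons; the profile has mean 1 over the
#' mask so the mask-mean trace equals the cell trace), plus
#' `neuropil_weight_true` times the local neuropil, plus Gaussian noise of
#' SD `config$noise_sd`. The red mean image shows PV somata near intensity
#' 1 and other cells near 0.15 (classification threshold 0.5), with thin
#' random red processes that PV classification must remove by morphology.
#'
#' @param cells list of [ground_truth_cell()]; footprints must not overlap.
#' @param traces numeric matrix frames x cells of noiseless cell
#'   fluorescence (from [spikes_to_fluorescence()]).
#' @param config a [session_config()].
#' @param rng_seed seed for noise, neuropil field and red processes.
#' @param neuropil_level mean neuropil fluorescence (a.u.); 0 disables the
#'   neuropil field entirely.
#' @param neuropil_spatial_amplitude relative SD of the smooth spatial
#'   variation of the neuropil map (0 = spatially flat field).
#' @return list with `movie` (array height x width x frames), `red`
#'   (matrix), `masks` (list of pixel-coordinate matrices per cell),
#'   `neuropil` (`spatial` map, `trace`), and `config`.
#' @export
render_session <- function(cells, traces, config,
                           rng_seed = config$rng_seed,
                           neuropil_level = 60,
                           neuropil_spatial_amplitude = 0.25) {
  field <- config$field_px
  n_frames <- nrow(traces)
  stopifnot(length(cells) == ncol(traces))
  masks <- vector("list", length(cells))
  profiles <- vector("list", length(cells))
  taken <- matrix(FALSE, field[1L], field[2L])
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    dp <- disc_pixels(cell$center_px,
                      cell$radius_um / config$pixel_size_um, field)
    if (nrow(dp$rc) == 0L) stop("cell ", i, " lies outside the field",
                                call. = FALSE)
    idx <- px_index(dp$rc, field[1L])
    if (any(taken[idx])) {
      stop("cell footprints overlap (cell ", i, ")", call. = FALSE)
    }
    taken[idx] <- TRUE
    p <- cell_profile(dp$dist, cell$radius_um / config$pixel_size_um,
                      cell$kind)
    masks[[i]] <- dp$rc
    profiles[[i]] <- p / mean(p)      # mask mean of profile = 1
  }

  np_spatial <- if (neuropil_level > 0) {
    neuropil_spatial_map(field, amplitude = neuropil_spatial_amplitude,
                         rng_seed = stage_seed(rng_seed, 1L))
  } else {
    matrix(0, field[1L], field[2L])
  }
  np_trace <- if (neuropil_level > 0) {
    neuropil_temporal_trace(n_frames, config$frame_rate_hz,
                            level = neuropil_level,
                            rng_seed = stage_seed(rng_seed, 2L))
  } else {
    numeric(n_frames)
  }

  npix <- prod(field)
  # background = full neuropil; cell pixels overwritten below
  movie <- array(as.vector(np_spatial) %o% np_trace,
                 dim = c(field[1L], field[2L], n_frames))
  w <- config$neuropil_weight_true
  for (i in seq_along(cells)) {
    idx <- px_index(masks[[i]], field[1L])
    # frames x pixels block for this cell
    block <- outer(traces[, i], profiles[[i]]) +
      w * outer(np_trace, np_spatial[idx])
    for (j in seq_along(idx)) {
      movie[idx[j] + npix * (seq_len(n_frames) - 1L)] <- block[, j]
    }
  }
  if (config$noise_sd > 0) {
    movie <- movie + with_seed(stage_seed(rng_seed, 3L),
      array(stats::rnorm(length(movie), 0, config$noise_sd), dim = dim(movie)))
  }

  red <- with_seed(stage_seed(rng_seed, 4L), {
    r <- matrix(pmax(stats::rnorm(npix, 0.05, 0.02), 0),
                field[1L], field[2L])
    # thin red processes: 1-px random lines
    for (k in seq_len(6L)) {
      row <- sample.int(field[1L], 1L)
      r[row, ] <- r[row, ] + 0.9
    }
    r
  })
  for (i in seq_along(cells)) {
    idx <- px_index(masks[[i]], field[1L])
    level <- if (cells[[i]]$cell_type == "pv") 1.0 else 0.15
    red[idx] <- level       # cytosolic label fills the soma
  }

  list(movie = movie, red = red, masks = masks,
       neuropil = list(spatial = np_spatial, trace = np_trace,
                       weight = w),
       config = config)
}

#' Place non-overlapping somata in the field
#'
#' Seeded rejection sampling of cell centers with a minimum center-to-center
#' separation; fails if the field cannot hold the requested count.
#'
#' @param n number of cells.
#' @param config a [session_config()].
#' @param radius_range_um soma radius range to sample uniformly.
#' @param margin_px margin kept free at the field border.
#' @param min_sep_um minimum center separation (defaults to slightly more
#'   than two maximal radii).
#' @param rng_seed seed.
#' @return list of `c(row, col)` centers and a vector of radii (um).
#' @export
place_cells <- function(n, config, radius_range_um = c(4.5, 7),
                        margin_px = 10, min_sep_um = NULL,
                        rng_seed = config$rng_seed) {
  field <- config$field_px
  px <- config$pixel_size_um
  if (is.null(min_sep_um)) min_sep_um <- 2.2 * radius_range_um[2L]
  with_seed(rng_seed, {
    centers <- matrix(NA_real_, 0L, 2L)
    radii <- numeric(0)
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place ", n, " non-overlapping cells in the field",
             call. = FALSE)
      }
      cand <- c(stats::runif(1, margin_px, field[1L] - margin_px),
                stats::runif(1, margin_px, field[2L] - margin_px))
      if (nrow(centers) > 0L) {
        d <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 2L,
                                            byrow = TRUE))^2))
        if (min(d) * px < min_sep_um) next
      }
      centers <- rbind(centers, cand)
      radii <- c(radii, stats::runif(1, radius_range_um[1L],
                                     radius_range_um[2L]))
    }
    list(centers = centers, radii = radii)
  })
}

#' Simulate a complete imaging session with ground truth
#'
#' Convenience driver used by the standard fixtures: places cells, builds
#' the stimulus schedule (or none, for a spontaneous session in darkness),
#' draws spikes, renders fluorescence and the movie, and generates
#' locomotion. Every intermediate ground-truth quantity is returned.
#'
#' @param config a [session_config()].
#' @param n_cells,n_pv number of somata and how many of them are PV+.
#' @param stimuli logical; include the size-series visual stimulation?
#' @param sizes,orientations stimulus parameter sets when `stimuli = TRUE`.
#' @param baseline_rate_hz spontaneous firing rate per cell (Hz).
#' @param evoked_peak_hz peak evoked firing rate at the preferred size (Hz).
#' @param dog_template [dog_params()] shape template for all cells (gains
#'   are rescaled per cell to hit `evoked_peak_hz`); default has
#'   center/surround constants a = 15, b = 45 deg and SSI near 0.48.
#' @param shared_mod_amplitude SD of the shared excitability modulation
#'   (0 disables it).
#' @param render logical; render the pixel movie (set `FALSE` for
#'   trace-level population sessions where only traces are analysed).
#' @param run_fraction expected running-time fraction for the locomotion
#'   trace.
#' @param rng_seed master seed; all stage seeds derive from it.
#' @return object of class `ca_session`: list with `config`, `timeline`,
#'   `cells`, `stim_log`, `spikes` (frames x cells), `traces` (noiseless
#'   fluorescence, frames x cells), `locomotion`, `shared_mod`, and (when
#'   rendered) `movie`, `red`, `masks`, `neuropil`.
#' @export
simulate_session <- function(config = session_config(),
                             n_cells = 20L, n_pv = 5L,
                             stimuli = TRUE,
                             sizes = seq(10, 60, 10), orientations = 0,
                             baseline_rate_hz = 0.03,
                             evoked_peak_hz = 4,
                             dog_template = dog_params(0, 1, 0.245, 15, 45),
                             shared_mod_amplitude = 0.3,
                             render = TRUE,
                             run_fraction = 0.15,
                             rng_seed = config$rng_seed) {
  timeline <- session_timeline(config)
  placed <- if (render) {
    place_cells(n_cells, config, rng_seed = stage_seed(rng_seed, 10L))
  } else {
    # trace-level session: geometry is unused, lay cells on a virtual grid
    k <- ceiling(sqrt(n_cells))
    g <- as.matrix(expand.grid(row = seq_len(k), col = seq_len(k)))[
      seq_len(n_cells), , drop = FALSE] * 20
    list(centers = g,
         radii = with_seed(stage_seed(rng_seed, 10L),
                           stats::runif(n_cells, 4.5, 7)))
  }

  # rescale the DoG template so the peak evoked rate is evoked_peak_hz
  peak <- max(dog_response(dog_template, seq(1, 60, 0.5)))
  sc <- evoked_peak_hz / peak
  cell_dog <- dog_params(dog_template$Rb * sc, dog_template$Ke * sc,
                         dog_template$Ki * sc, dog_template$a,
                         dog_template$b)

  pv_idx <- if (n_pv > 0) seq_len(n_pv) else integer(0)
  cells <- lapply(seq_len(n_cells), function(i) {
    ground_truth_cell(
      center_px = placed$centers[i, ], radius_um = placed$radii[i],
      kind = "soma",
      cell_type = if (i %in% pv_idx) "pv" else "pyramidal",
      baseline_rate_hz = baseline_rate_hz,
      dog_params = cell_dog,
      pref_orientation_deg = with_seed(stage_seed(rng_seed, 20L + i),
                                       stats::runif(1, 0, 180)))
  })

  stim_log <- if (stimuli) {
    generate_stimulus_schedule(config, sizes, orientations,
                               rng_seed = stage_seed(rng_seed, 30L))
  } else {
    NULL
  }
  shared_mod <- if (shared_mod_amplitude > 0) {
    generate_shared_modulation(config, amplitude = shared_mod_amplitude,
                               rng_seed = stage_seed(rng_seed, 40L))
  } else {
    NULL
  }
  spikes <- vapply(seq_len(n_cells), function(i) {
    generate_spikes(cells[[i]], stim_log, timeline, config,
                    rng_seed = stage_seed(rng_seed, 100L + i),
                    rate_modulation = shared_mod)
  }, numeric(timeline$n_frames))
  traces <- apply(spikes, 2L, spikes_to_fluorescence, config = config)

  locomotion <- generate_locomotion(config, run_fraction = run_fraction,
                                    rng_seed = stage_seed(rng_seed, 50L))

  out <- list(config = config, timeline = timeline, cells = cells,
              stim_log = stim_log, spikes = spikes, traces = traces,
              locomotion = locomotion, shared_mod = shared_mod)
  if (render) {
    out <- c(out, render_session(cells, traces, config,
                                 rng_seed = stage_seed(rng_seed, 60L)))
    out$config <- config
  }
  structure(out, class = "ca_session")
}

#' @export
print.ca_session <- function(x, ...) {
  cat(sprintf(
    "Synthetic session: %d cells (%d PV), %d frames @ %.3g Hz, treatment %s (gain %.2f)%s\n",
    length(x$cells), sum(vapply(x$cells, function(c) c$cell_type == "pv",
                                logical(1))),
    x$timeline$n_frames, x$config$frame_rate_hz, x$config$treatment,
    x$config$drug_gain,
    if (is.null(x$movie)) " [trace-level]" else " [rendered]"))
  invisible(x)
}
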