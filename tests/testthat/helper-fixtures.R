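# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The standard rendered 20-cell imaging fixture (fixed seed 42).
imaging_fixture <- function() {
  cached("imaging", function() standard_imaging_session(rng_seed = 42L))
}

# Its segmentation, reused by several test files.
imaging_fixture_rois <- function() {
  cached("imaging_rois", function() {
    ses <- imaging_fixture()
    classify_pv(ses$red, detect_somata(ses$movie))
  })
}

# Small config for fast unit tests.
tiny_config <- function(noise_sd = 0, ...) {
  session_config(field_px = c(48L, 48L), baseline_duration_s = 10,
                 post_duration_s = 14, noise_sd = noise_sd, rng_seed = 7L,
                 ...)
}

# Ground-truth ROI list from a session's masks.
gt_rois <- function(session) {
  lapply(seq_along(session$masks), function(i) {
    structure(list(id = i, pixels = session$masks[[i]], kind = "soma",
                   cell_type = session$cells[[i]]$cell_type,
                   quality = NA_real_), class = "roi_mask")
  })
}

# Ground-truth dF/F of cell i computed from the generator's noiseless
# fluorescence with the same baseline-median convention as the pipeline.
gt_dff <- function(session, i) {
  compute_dff(session$traces[, i], session$timeline$baseline_frames)$values
}
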