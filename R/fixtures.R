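# Standard synthetic fixtures. These fix the study conditions under which
# the pipeline is validated; tests, the analysis scripts and the
# acceptance script all build their sessions through these two functions
# so that every stage is exercised under identical conditions.

#' Standard rendered imaging fixture (20 somata)
#'
#' A short rendered session used to validate the pixel-level stages:
#' registration, segmentation, PV classification and neuropil-corrected
#' trace extraction. 20 somata (5 PV+) in a 140 x 140 um field, 150 s at
#' 10 Hz, spontaneous activity at 0.4 Hz (an active-period rate that gives
#' correlation-based segmentation enough transients in a short movie),
#' shared modulation on, default pixel noise.
#'
#' @param rng_seed master seed.
#' @param noise_sd pixel noise SD (a.u.).
#' @param n_cells,n_pv cell counts.
#' @return a rendered `ca_session`.
#' @export
standard_imaging_session <- function(rng_seed = 42L, noise_sd = 2,
                                     n_cells = 20L, n_pv = 5L) {
  cfg <- session_config(field_px = c(140L, 140L),
                        baseline_duration_s = 60, post_duration_s = 90,
                        noise_sd = noise_sd, rng_seed = rng_seed)
  simulate_session(cfg, n_cells = n_cells, n_pv = n_pv, stimuli = FALSE,
                   baseline_rate_hz = 0.4, render = TRUE,
                   rng_seed = rng_seed)
}

#' Standard trace-level population session (200 cells)
#'
#' The drug-epoch fixture: 200 cells (40 PV+), full 6-minute baseline and
#' 45-minute post epochs at 10 Hz, spontaneous activity at 0.03 Hz (sparse
#' firing in darkness, the regime in which the baseline-median F0
#' convention is unbiased), shared excitability modulation and locomotion
#' bouts on, no movie rendering.
#'
#' @param treatment treatment label (sets the default drug gain).
#' @param drug_gain overrides the treatment's default gain when given.
#' @param rng_seed master seed.
#' @return a trace-level `ca_session`.
#' @export
standard_population_session <- function(treatment = "saline",
                                        drug_gain = NULL,
                                        rng_seed = 1L) {
  cfg <- session_config(treatment = treatment, drug_gain = drug_gain,
                        rng_seed = rng_seed)
  simulate_session(cfg, n_cells = 200L, n_pv = 40L, stimuli = FALSE,
                   render = FALSE, rng_seed = rng_seed)
}

#' Standard evoked-activity session (size-tuning fixture)
#'
#' Trace-level session with the full size-series visual stimulation
#' (10-60 degrees, horizontal gratings): the input to the evoked-response
#' and size-tuning stages. Uses a higher evoked rate than spontaneous so
#' trial amplitudes are resolvable, and the default DoG tuning template
#' (surround suppression index near 0.48).
#'
#' @param treatment treatment label.
#' @param drug_gain optional gain override.
#' @param n_cells number of cells.
#' @param rng_seed master seed.
#' @return a trace-level `ca_session` with a stimulus log.
#' @export
standard_evoked_session <- function(treatment = "saline",
                                    drug_gain = NULL, n_cells = 50L,
                                    rng_seed = 1L) {
  cfg <- session_config(treatment = treatment, drug_gain = drug_gain,
                        rng_seed = rng_seed)
  simulate_session(cfg, n_cells = n_cells, n_pv = 0L, stimuli = TRUE,
                   sizes = seq(10, 60, 10), orientations = 0,
                   baseline_rate_hz = 0.03, evoked_peak_hz = 4,
                   render = FALSE, rng_seed = rng_seed)
}
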