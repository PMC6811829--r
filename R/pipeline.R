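# End-to-end session analysis drivers tying the stages together. The
# imaging pipeline runs on rendered movies (registration -> segmentation ->
# traces); the trace-level pipeline runs population statistics on sessions
# where only fluorescence traces are simulated.

#' Analyze a rendered synthetic imaging session end to end
#'
#' Registration (to the post-epoch mean), soma segmentation, PV
#' classification, neuropil-corrected dF/F extraction, stationary masking,
#' per-ROI and population fractional changes, and (when the session has
#' visual stimuli) size-tuning curves with DoG fits per epoch. Fully
#' deterministic: the same session object yields the same result list.
#'
#' @param session a rendered `ca_session` from [simulate_session()].
#' @param register run rigid registration (skippable for jitter-free
#'   synthetic movies to save time)?
#' @param corr_threshold,min_area_px,max_area_px segmentation parameters.
#' @param weight neuropil correction weight.
#' @param speed_threshold,pad_s stationary-mask parameters.
#' @param fit_seed seed for the DoG multi-start fits.
#' @return list with segmentation results, traces, fractional changes,
#'   tuning fits and provenance fields, directly consumable by
#'   [build_report()].
#' @export
analyze_session <- function(session, register = TRUE,
                            corr_threshold = 0.4, min_area_px = 30L,
                            max_area_px = 400L, weight = 0.7,
                            speed_threshold = 1, pad_s = 1,
                            fit_seed = 1L) {
  cfg <- session$config
  tl <- session$timeline
  movie <- session$movie
  if (register) {
    reg <- register_movie(movie, timeline = tl)
    movie <- reg$movie
    shifts <- reg$shifts
  } else {
    shifts <- NULL
  }
  rois <- detect_somata(movie, corr_threshold = corr_threshold,
                        min_area_px = min_area_px,
                        max_area_px = max_area_px)
  rois <- classify_pv(session$red, rois)
  tr <- extract_session_traces(movie, rois, tl, weight = weight,
                               pixel_size_um = cfg$pixel_size_um)
  stat_mask <- stationary_mask(session$locomotion, cfg$frame_rate_hz,
                               speed_threshold, pad_s)
  dff_ok <- tr$dff[, tr$included, drop = FALSE]
  roi_fc <- apply(dff_ok, 2L, fractional_change, timeline = tl,
                  stationary = stat_mask)
  pop <- population_mean(dff_ok, cfg$frame_rate_hz)
  pop_fc <- fractional_change(pop$raw, tl, stationary = stat_mask)

  tuning <- NULL
  if (!is.null(session$stim_log)) {
    resp <- trial_responses(dff_ok, session$stim_log, cfg$frame_rate_hz,
                            stationary = stat_mask)
    pre_curve <- population_size_curve(resp, session$stim_log,
                                       epoch_frames = tl$baseline_frames)
    post_curve <- population_size_curve(resp, session$stim_log,
                                        epoch_frames = tl$analysis_window)
    tuning <- list(
      pre = pre_curve, post = post_curve,
      fit_pre = fit_dog(pre_curve$size_deg, pre_curve$mean_response,
                        seed = fit_seed),
      fit_post = fit_dog(post_curve$size_deg, post_curve$mean_response,
                         seed = fit_seed))
  }

  list(treatment = cfg$treatment,
       n_rois = sum(tr$included),
       rois = rois, traces = tr, shifts = shifts,
       stationary = stat_mask,
       roi_fractional_change = as.numeric(roi_fc),
       population_fractional_change = as.numeric(pop_fc),
       tuning = tuning,
       ssi_pre = if (!is.null(tuning) && tuning$fit_pre$converged)
         tuning$fit_pre$ssi else NULL,
       ssi_post = if (!is.null(tuning) && tuning$fit_post$converged)
         tuning$fit_post$ssi else NULL,
       seed = cfg$rng_seed, config_hash = hash_config(cfg))
}

#' Analyze a trace-level population session
#'
#' For sessions simulated without movie rendering (hundreds of cells,
#' 45-minute epochs): converts each cell's fluorescence trace to dF/F with
#' the baseline-median convention, computes per-ROI and population
#' fractional changes restricted to stationary frames, and E/I population
#' correlation and coupling when both cell types are present.
#'
#' @param session a trace-level `ca_session`
#'   (`simulate_session(..., render = FALSE)`).
#' @param speed_threshold,pad_s stationary-mask parameters.
#' @return result list consumable by [build_report()].
#' @export
analyze_population_session <- function(session, speed_threshold = 1,
                                       pad_s = 1) {
  cfg <- session$config
  tl <- session$timeline
  base <- tl$baseline_frames
  dff <- apply(session$traces, 2L, function(tr) {
    compute_dff(tr, base)$values
  })
  stat_mask <- stationary_mask(session$locomotion, cfg$frame_rate_hz,
                               speed_threshold, pad_s)
  roi_fc <- apply(dff, 2L, fractional_change, timeline = tl,
                  stationary = stat_mask)
  pop <- population_mean(dff, cfg$frame_rate_hz)
  pop_fc <- fractional_change(pop$raw, tl, stationary = stat_mask)

  types <- vapply(session$cells, function(c) c$cell_type, character(1))
  ei <- NULL
  if (any(types == "pv") && any(types == "pyramidal")) {
    exc <- population_mean(dff[, types == "pyramidal", drop = FALSE],
                           cfg$frame_rate_hz)
    inh <- population_mean(dff[, types == "pv", drop = FALSE],
                           cfg$frame_rate_hz)
    ei <- list(
      r_baseline = as.numeric(ei_correlation(exc$raw, inh$raw,
                                             tl$baseline_frames)),
      r_post = as.numeric(ei_correlation(exc$raw, inh$raw,
                                         tl$post_frames)),
      coupling = ei_coupling(exc$raw + 1, inh$raw + 1,
                             tl$baseline_frames, cfg$frame_rate_hz))
  }

  list(treatment = cfg$treatment, n_rois = ncol(dff),
       dff = dff, stationary = stat_mask,
       roi_fractional_change = as.numeric(roi_fc),
       population_fractional_change = as.numeric(pop_fc),
       ei_r_baseline = if (!is.null(ei)) ei$r_baseline else NULL,
       ei_r_post = if (!is.null(ei)) ei$r_post else NULL,
       ei_coupling = if (!is.null(ei)) ei$coupling else NULL,
       seed = cfg$rng_seed, config_hash = hash_config(cfg))
}
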