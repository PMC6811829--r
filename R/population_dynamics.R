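# Population activity time courses, locomotion epoching, pre/post drug
# fractional change, and excitatory/inhibitory correlation and coupling.

#' Smoothed population mean trace
#'
#' Unweighted mean dF/F across ROIs per frame, smoothed with a centered
#' boxcar sliding window (default 2.5 minutes), truncated at the edges.
#'
#' @param dff frames x ROI matrix of dF/F (NA columns are dropped).
#' @param frame_rate_hz frame rate.
#' @param window_s smoothing window in seconds (150 = 2.5 min).
#' @return list with `values` (per frame), `n_rois`, `window_s`.
#' @export
population_mean <- function(dff, frame_rate_hz, window_s = 150) {
  dff <- as.matrix(dff)
  keep <- colSums(is.na(dff)) == 0L
  if (!any(keep)) stop("no included traces", call. = FALSE)
  m <- rowMeans(dff[, keep, drop = FALSE])
  list(values = moving_average(m, s_to_frames(window_s, frame_rate_hz)),
       raw = m, n_rois = sum(keep), window_s = window_s)
}

#' Stationary-frame mask from a locomotion trace
#'
#' A frame is stationary iff the speed is at or below `speed_threshold`
#' there and in every frame within `pad_s` seconds of it (running bouts
#' are padded on both sides).
#'
#' @param speed speed per frame (cm/s).
#' @param frame_rate_hz frame rate.
#' @param speed_threshold running threshold (cm/s).
#' @param pad_s padding around running bouts (s).
#' @return logical vector, `TRUE` = stationary.
#' @export
stationary_mask <- function(speed, frame_rate_hz, speed_threshold = 1,
                            pad_s = 1) {
  if (speed_threshold < 0) stop("speed_threshold must be >= 0",
                                call. = FALSE)
  running <- speed > speed_threshold
  pad <- s_to_frames(pad_s, frame_rate_hz)
  if (pad > 0L && any(running)) {
    idx <- which(running)
    ext <- unique(unlist(lapply(idx, function(i)
      max(1L, i - pad):min(length(speed), i + pad))))
    running[ext] <- TRUE
  }
  !running
}

#' Fractional change of activity between baseline and the analysis window
#'
#' `(mean(post analysis window, stationary) - mean(baseline, stationary))
#'  / mean(baseline, stationary)`; a drug that multiplies activity by g
#' yields g - 1.
#'
#' @param values per-frame activity (dF/F of one ROI, or a population
#'   trace).
#' @param timeline [session_timeline()].
#' @param stationary logical per-frame mask (`NULL` = all stationary).
#' @return scalar fractional change; `NA` with a `"reason"` attribute when
#'   the baseline mean is not positive or a window has no stationary
#'   frames.
#' @export
fractional_change <- function(values, timeline, stationary = NULL) {
  n <- length(values)
  if (is.null(stationary)) stationary <- rep(TRUE, n)
  in_win <- function(win) {
    idx <- (win[1L] + 1L):min(win[2L], n)
    idx[stationary[idx]]
  }
  b <- in_win(timeline$baseline_frames)
  p <- in_win(timeline$analysis_window)
  if (length(b) == 0L || length(p) == 0L) {
    return(structure(NA_real_, reason = "no stationary frames in a window"))
  }
  mb <- mean(values[b])
  if (!is.finite(mb) || mb <= 0) {
    return(structure(NA_real_, reason = "nonpositive baseline mean"))
  }
  (mean(values[p]) - mb) / mb
}

#' Pearson correlation of excitatory and inhibitory population traces
#'
#' Correlates the two unsmoothed population mean traces over a frame
#' window.
#'
#' @param exc,inh per-frame population traces (unsmoothed means).
#' @param window half-open 0-based frame interval `c(first, end)`.
#' @return Pearson r; `NA` with a `"reason"` attribute if either trace is
#'   constant in the window.
#' @export
ei_correlation <- function(exc, inh, window) {
  idx <- (window[1L] + 1L):min(window[2L], length(exc))
  if (length(idx) < 3L) stop("window must span at least 3 frames",
                             call. = FALSE)
  x <- exc[idx]; y <- inh[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, reason = "constant trace in window"))
  }
  stats::cor(x, y)
}

#' Excitatory/inhibitory coupling ratio time course
#'
#' Both population traces are smoothed with a short sliding window
#' (default 5 s), normalized to their own baseline-period mean (so
#' baseline differences in absolute activity cancel), and divided
#' elementwise (E/I). Frames where the normalized inhibitory trace is not
#' positive are returned as `NA` and counted in `n_undefined`. Any gain
#' applied to both populations cancels.
#'
#' @param exc,inh per-frame population traces.
#' @param baseline_frames half-open 0-based baseline interval.
#' @param frame_rate_hz frame rate.
#' @param window_s smoothing window (s).
#' @return list with `ratio` (per frame), `n_undefined`.
#' @export
ei_coupling <- function(exc, inh, baseline_frames, frame_rate_hz,
                        window_s = 5) {
  w <- s_to_frames(window_s, frame_rate_hz)
  es <- moving_average(exc, w); is_ <- moving_average(inh, w)
  bidx <- (baseline_frames[1L] + 1L):min(baseline_frames[2L], length(exc))
  eb <- mean(es[bidx]); ib <- mean(is_[bidx])
  if (eb <= 0 || ib <= 0) {
    stop("baseline means must be positive for E/I coupling", call. = FALSE)
  }
  en <- es / eb; inorm <- is_ / ib
  ratio <- ifelse(inorm > 0, en / inorm, NA_real_)
  list(ratio = ratio, n_undefined = sum(!is.finite(ratio)))
}
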