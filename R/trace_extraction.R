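# Raw trace extraction, neuropil correction, the >5% brightness inclusion
# filter, and dF/F conversion.

#' Extract the raw trace of an ROI or annulus
#'
#' Per-frame unweighted mean over the mask pixels.
#'
#' @param movie array height x width x frames.
#' @param pixels pixel coordinate matrix (row, col), or a `roi_mask` /
#'   annulus object with a `$pixels` field.
#' @return numeric vector, one value per frame.
#' @export
extract_raw <- function(movie, pixels) {
  if (is.list(pixels)) pixels <- pixels$pixels
  d <- dim(movie)
  if (any(pixels[, 1L] < 1L | pixels[, 1L] > d[1L] |
          pixels[, 2L] < 1L | pixels[, 2L] > d[2L])) {
    stop("mask pixels outside the movie frame", call. = FALSE)
  }
  idx <- px_index(pixels, d[1L])
  flat <- matrix(movie, prod(d[1:2]), d[3L])
  colMeans(flat[idx, , drop = FALSE])
}

#' Neuropil-correct a soma trace
#'
#' Subtracts the annulus (neuropil) trace from the soma trace with the
#' given weight: `corrected = soma - weight * annulus`, elementwise. The
#' default weight is 0.7. Corrected fluorescence may transiently go
#' negative; it is deliberately not clipped.
#'
#' @param soma,annulus numeric traces of equal length.
#' @param weight neuropil weight in `[0, 1]`.
#' @return corrected trace.
#' @export
neuropil_correct <- function(soma, annulus, weight = 0.7) {
  if (length(soma) != length(annulus)) {
    stop("soma and annulus traces differ in length", call. = FALSE)
  }
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]",
                                     call. = FALSE)
  soma - weight * annulus
}

#' Soma brightness inclusion filter
#'
#' A cell is included only when its soma is more than 5% brighter than the
#' surrounding neuropil over the baseline epoch: strictly
#' `mean(soma) > 1.05 * mean(annulus)` (a soma exactly 5% brighter is
#' excluded).
#'
#' @param soma,annulus raw traces over the baseline epoch.
#' @param min_ratio brightness ratio that must be strictly exceeded.
#' @return logical scalar.
#' @export
brightness_filter <- function(soma, annulus, min_ratio = 1.05) {
  mean(soma) > min_ratio * mean(annulus)
}

#' Convert a raw trace to dF/F
#'
#' The denominator `f0` is the median of the raw trace over the baseline
#' frame interval; `dF/F = (F - f0)/f0`. A non-positive `f0` marks the ROI
#' excluded (the values are returned as `NA`) rather than producing
#' unusable ratios; frames where dF/F falls below -1 are counted in the
#' `n_below_minus1` field.
#'
#' @param trace raw (typically neuropil-corrected) fluorescence trace.
#' @param baseline_frames half-open 0-based frame interval `c(first, end)`
#'   defining the baseline period.
#' @return list with `values` (dF/F per frame), `f0`, `included`, `reason`
#'   (when excluded), `n_below_minus1`.
#' @export
compute_dff <- function(trace, baseline_frames) {
  idx <- (baseline_frames[1L] + 1L):baseline_frames[2L]
  if (length(idx) < 1L || baseline_frames[2L] <= baseline_frames[1L]) {
    stop("empty baseline interval", call. = FALSE)
  }
  f0 <- stats::median(trace[idx])
  if (!is.finite(f0) || f0 <= 0) {
    return(list(values = rep(NA_real_, length(trace)), f0 = f0,
                included = FALSE, reason = "nonpositive baseline median",
                n_below_minus1 = NA_integer_))
  }
  v <- (trace - f0) / f0
  list(values = v, f0 = f0, included = TRUE, reason = NULL,
       n_below_minus1 = sum(v < -1))
}

#' Extract neuropil-corrected dF/F for every ROI of a movie
#'
#' Convenience driver for the full trace stage: builds each ROI's annulus,
#' extracts soma and annulus traces, applies the brightness filter over
#' the baseline epoch, neuropil-corrects and converts to dF/F.
#'
#' @param movie registered movie.
#' @param rois list of `roi_mask`.
#' @param timeline [session_timeline()] (supplies the baseline epoch).
#' @param weight neuropil correction weight.
#' @param radius_um annulus radius (um).
#' @param pixel_size_um microns per pixel.
#' @return list with `dff` (frames x ROI matrix, excluded ROIs all-NA),
#'   `included` (logical), `f0`, `soma`, `annulus` (raw trace matrices),
#'   `reasons` (list).
#' @export
extract_session_traces <- function(movie, rois, timeline, weight = 0.7,
                                   radius_um = 30, pixel_size_um = 1) {
  d <- dim(movie)
  n_roi <- length(rois)
  base <- timeline$baseline_frames
  bidx <- (base[1L] + 1L):min(base[2L], d[3L])
  soma <- annulus <- dff <- matrix(NA_real_, d[3L], n_roi)
  included <- logical(n_roi); f0 <- rep(NA_real_, n_roi)
  reasons <- vector("list", n_roi)
  for (i in seq_len(n_roi)) {
    ann <- build_annulus(rois[[i]], rois, radius_um = radius_um,
                         pixel_size_um = pixel_size_um, field_px = d[1:2])
    soma[, i] <- extract_raw(movie, rois[[i]])
    annulus[, i] <- extract_raw(movie, ann)
    if (!brightness_filter(soma[bidx, i], annulus[bidx, i])) {
      reasons[[i]] <- "soma not >5% brighter than neuropil"
      next
    }
    corrected <- neuropil_correct(soma[, i], annulus[, i], weight)
    res <- compute_dff(corrected, c(base[1L], min(base[2L], d[3L])))
    if (!res$included) {
      reasons[[i]] <- res$reason
      next
    }
    dff[, i] <- res$values
    f0[i] <- res$f0
    included[i] <- TRUE
  }
  colnames(dff) <- vapply(rois, function(r) as.character(r$id),
                          character(1))
  list(dff = dff, included = included, f0 = f0, soma = soma,
       annulus = annulus, reasons = reasons)
}
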