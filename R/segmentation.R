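# ROI detection: correlation-based soma segmentation, intensity-based
# bouton detection, red-channel PV classification and neuropil annuli.

#' ROI mask constructor
#' @noRd
roi_mask <- function(id, pixels, kind = "soma", cell_type = "unknown",
                     quality = NA_real_) {
  structure(list(id = id, pixels = pixels, kind = kind,
                 cell_type = cell_type, quality = quality),
            class = "roi_mask")
}

#' 4-connected neighbors of a pixel set, clipped to the field
#' @noRd
neighbors4 <- function(rc, field) {
  cand <- rbind(cbind(rc[, 1L] - 1L, rc[, 2L]),
                cbind(rc[, 1L] + 1L, rc[, 2L]),
                cbind(rc[, 1L], rc[, 2L] - 1L),
                cbind(rc[, 1L], rc[, 2L] + 1L))
  keep <- cand[, 1L] >= 1L & cand[, 1L] <= field[1L] &
          cand[, 2L] >= 1L & cand[, 2L] <= field[2L]
  unique(cand[keep, , drop = FALSE])
}

#' Detect soma ROIs by grouping pixels with correlated time courses
#'
#' Fully automated, deterministic variant of correlation-based soma
#' segmentation: candidate seed pixels are taken in decreasing
#' temporal-variance order (above the `seed_quantile` variance quantile);
#' each seed grows greedily by repeatedly adding unassigned 4-connected
#' border pixels whose time-course Pearson correlation with the current
#' ROI mean trace exceeds `corr_threshold`. Grown regions outside
#' `[min_area_px, max_area_px]` are discarded. The ROI quality score is
#' the mean correlation of member-pixel traces with the ROI mean trace.
#'
#' Correlation and variance are computed on temporally high-pass filtered
#' pixel traces (the per-pixel trace minus its own `highpass_s` moving
#' average), which removes the slow shared neuropil component that would
#' otherwise correlate neighboring background pixels; set `highpass_s = 0`
#' to disable.
#'
#' @param movie registered movie, height x width x frames (>= 100 frames).
#' @param corr_threshold Pearson correlation needed to join an ROI.
#' @param min_area_px,max_area_px accepted ROI area bounds (pixels).
#' @param seed_quantile variance quantile above which pixels may seed ROIs.
#' @param highpass_s moving-average window (s) subtracted from each pixel
#'   trace before correlation; long relative to a calcium transient, short
#'   relative to neuropil drift.
#' @param frame_rate_hz frame rate, needed when `highpass_s > 0`.
#' @return list of `roi_mask` objects (possibly empty), pixel sets
#'   mutually disjoint and 4-connected.
#' @export
detect_somata <- function(movie, corr_threshold = 0.4,
                          min_area_px = 30L, max_area_px = 400L,
                          seed_quantile = 0.9, highpass_s = 10,
                          frame_rate_hz = 10) {
  d <- dim(movie)
  if (d[3L] < 100L) stop("need at least 100 frames to segment by correlation",
                         call. = FALSE)
  field <- d[1:2]
  npix <- prod(field)
  flat <- matrix(movie, npix, d[3L])       # pixels x frames
  if (highpass_s > 0) {
    flat <- highpass_rows(flat, s_to_frames(highpass_s, frame_rate_hz))
  }
  v <- matrixStats_rowVars(flat)
  if (max(v) == 0) return(list())
  vq <- stats::quantile(v[v > 0], seed_quantile)
  seeds <- order(v, decreasing = TRUE)
  seeds <- seeds[v[seeds] > vq]
  assigned <- logical(npix)
  in_roi <- logical(npix)
  rois <- list()
  for (s in seeds) {
    if (assigned[s]) next
    members <- s
    in_roi[s] <- TRUE
    mean_tr <- flat[s, ]
    frontier <- members
    repeat {
      rc <- cbind((frontier - 1L) %% field[1L] + 1L,
                  (frontier - 1L) %/% field[1L] + 1L)
      cand <- neighbors4(rc, field)
      ci <- px_index(cand, field[1L])
      ci <- ci[!assigned[ci] & !in_roi[ci]]
      if (length(ci) == 0L) break
      cors <- suppressWarnings(
        as.vector(stats::cor(mean_tr, t(flat[ci, , drop = FALSE]))))
      add <- ci[!is.na(cors) & cors > corr_threshold]
      if (length(add) == 0L) break
      members <- c(members, add)
      in_roi[add] <- TRUE
      frontier <- add
      if (length(members) > max_area_px) break
      mean_tr <- colMeans(flat[members, , drop = FALSE])
    }
    in_roi[members] <- FALSE
    if (length(members) >= min_area_px && length(members) <= max_area_px) {
      assigned[members] <- TRUE
      rc <- cbind(row = (members - 1L) %% field[1L] + 1L,
                  col = (members - 1L) %/% field[1L] + 1L)
      q <- mean(suppressWarnings(
        as.vector(stats::cor(mean_tr, t(flat[members, , drop = FALSE])))),
        na.rm = TRUE)
      rois[[length(rois) + 1L]] <-
        roi_mask(length(rois) + 1L, rc, kind = "soma", quality = q)
    }
  }
  rois
}

#' Subtract a per-row moving average (temporal high-pass) from a
#' pixels x frames matrix
#' @noRd
highpass_rows <- function(m, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(m - rowMeans(m))
  n <- ncol(m)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  m - (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
}

#' Row variances without extra dependencies
#' @noRd
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Detect bouton ROIs from a mean image
#'
#' Automated stand-in for manual bouton annotation: thresholds the mean
#' image at the given intensity percentile and keeps connected components
#' within the area bounds as bouton ROIs (flagged `automated` in the ROI
#' metadata written by [write_rois_json()]).
#'
#' @param mean_image numeric matrix (time-averaged movie frame).
#' @param intensity_percentile percentile (0-100) of the threshold.
#' @param min_area_px,max_area_px accepted component areas.
#' @return list of `roi_mask` objects with `kind = "bouton"`.
#' @export
detect_boutons <- function(mean_image, intensity_percentile = 99,
                           min_area_px = 1L, max_area_px = 20L) {
  stopifnot(all(is.finite(mean_image)))
  thr <- stats::quantile(mean_image, intensity_percentile / 100)
  bw <- mean_image > thr
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  rois <- list()
  for (l in seq_len(max(labm))) {
    w <- which(labm == l, arr.ind = TRUE)
    if (nrow(w) >= min_area_px && nrow(w) <= max_area_px) {
      colnames(w) <- c("row", "col")
      rois[[length(rois) + 1L]] <-
        roi_mask(length(rois) + 1L, w, kind = "bouton")
    }
  }
  rois
}

#' Classify PV+ cells from the red channel
#'
#' Thresholds the mean registered red-channel image, then erodes and
#' dilates the binary mask (disc structuring elements) to remove thin
#' labeled processes, and labels an ROI `pv` when at least
#' `overlap_fraction` of its pixels fall inside the cleaned mask
#' (`putative_pyramidal` otherwise). Raising `red_threshold` can only
#' remove pv labels, never add them.
#'
#' @param red_mean_image red-channel mean image aligned to the green movie.
#' @param rois list of `roi_mask`.
#' @param red_threshold intensity threshold on the red image.
#' @param erosion_radius_px,dilation_radius_px morphology radii (pixels).
#' @param overlap_fraction minimum fraction of ROI pixels inside the red
#'   mask for a `pv` call.
#' @return the ROI list with `cell_type` set on every ROI.
#' @export
classify_pv <- function(red_mean_image, rois, red_threshold = 0.5,
                        erosion_radius_px = 2L, dilation_radius_px = 2L,
                        overlap_fraction = 0.5) {
  bw <- EBImage::Image((red_mean_image > red_threshold) * 1)
  if (erosion_radius_px > 0) {
    bw <- EBImage::erode(bw, EBImage::makeBrush(2L * erosion_radius_px + 1L,
                                                shape = "disc"))
  }
  if (dilation_radius_px > 0) {
    bw <- EBImage::dilate(bw, EBImage::makeBrush(2L * dilation_radius_px + 1L,
                                                 shape = "disc"))
  }
  mask <- as.matrix(EBImage::imageData(bw)) > 0
  lapply(rois, function(r) {
    idx <- px_index(r$pixels, nrow(mask))
    frac <- mean(mask[idx])
    r$cell_type <- if (frac >= overlap_fraction) "pv" else
      "putative_pyramidal"
    r
  })
}

#' Build the neuropil annulus around an ROI
#'
#' All pixels within `radius_um` of any pixel of the ROI, excluding the
#' pixels of every ROI in `all_rois`. Fails with the ROI id if nothing
#' remains (densely packed fields).
#'
#' @param roi the `roi_mask` to surround.
#' @param all_rois every ROI in the field (pixels excluded from the
#'   annulus).
#' @param radius_um annulus radius in microns (default 30).
#' @param pixel_size_um microns per pixel.
#' @param field_px `c(height, width)` of the movie.
#' @return list with `roi_id` and `pixels` (matrix row/col).
#' @export
build_annulus <- function(roi, all_rois, radius_um = 30, pixel_size_um = 1,
                          field_px) {
  r_px <- radius_um / pixel_size_um
  rr <- range(roi$pixels[, 1L]); cr <- range(roi$pixels[, 2L])
  rows <- max(1L, floor(rr[1L] - r_px)):min(field_px[1L], ceiling(rr[2L] + r_px))
  cols <- max(1L, floor(cr[1L] - r_px)):min(field_px[2L], ceiling(cr[2L] + r_px))
  g <- as.matrix(expand.grid(row = rows, col = cols))
  # distance to nearest ROI pixel
  d2 <- matrix(Inf, nrow(g), 1L)
  for (k in seq_len(nrow(roi$pixels))) {
    d2 <- pmin(d2, (g[, 1L] - roi$pixels[k, 1L])^2 +
                   (g[, 2L] - roi$pixels[k, 2L])^2)
  }
  keep <- d2 <= r_px^2
  ann <- g[keep, , drop = FALSE]
  excl <- do.call(rbind, lapply(all_rois, function(x) x$pixels))
  if (!is.null(excl) && nrow(excl) > 0L) {
    ann_id <- px_index(ann, field_px[1L])
    excl_id <- px_index(excl, field_px[1L])
    ann <- ann[!(ann_id %in% excl_id), , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    stop("empty neuropil annulus for ROI ", roi$id, call. = FALSE)
  }
  list(roi_id = roi$id, pixels = ann)
}

#' Match detected ROIs against ground-truth masks by IoU
#'
#' Greedy one-to-one assignment in decreasing IoU order, keeping pairs
#' with IoU at or above the threshold (at this threshold the greedy
#' matching is the optimal assignment, since no two detections can both
#' overlap one truth mask by more than half).
#'
#' @param detected list of `roi_mask`.
#' @param truth list of ground-truth pixel matrices (row/col).
#' @param field_px field dimensions.
#' @param iou_threshold minimum IoU to count a match.
#' @return list with `matches` (data frame det/truth/iou), `precision`,
#'   `recall`.
#' @export
match_rois <- function(detected, truth, field_px, iou_threshold = 0.5) {
  det_idx <- lapply(detected, function(r) px_index(r$pixels, field_px[1L]))
  tru_idx <- lapply(truth, function(p) px_index(p, field_px[1L]))
  pairs <- expand.grid(det = seq_along(det_idx), tru = seq_along(tru_idx))
  if (nrow(pairs) == 0L) {
    return(list(matches = data.frame(), precision = 0,
                recall = if (length(truth)) 0 else NA_real_))
  }
  pairs$iou <- mapply(function(i, j) {
    a <- det_idx[[i]]; b <- tru_idx[[j]]
    length(intersect(a, b)) / length(union(a, b))
  }, pairs$det, pairs$tru)
  pairs <- pairs[pairs$iou >= iou_threshold, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou), , drop = FALSE]
  used_d <- used_t <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$det[i] %in% used_d) && !(pairs$tru[i] %in% used_t)) {
      keep[i] <- TRUE
      used_d <- c(used_d, pairs$det[i]); used_t <- c(used_t, pairs$tru[i])
    }
  }
  m <- pairs[keep, , drop = FALSE]
  list(matches = m,
       precision = if (length(detected)) nrow(m) / length(detected)
                   else NA_real_,
       recall = if (length(truth)) nrow(m) / length(truth) else NA_real_)
}
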