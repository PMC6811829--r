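# Disk interfaces: 16-bit TIFF movies, label images, ROI JSON, CSV logs.

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' Values are scaled linearly by `scale` (a.u. per grey level) and clipped
#' to the 16-bit range; the scale is stored nowhere, so keep it with the
#' session config for quantitative round trips.
#'
#' @param movie array height x width x frames.
#' @param path output file.
#' @param scale divisor mapping fluorescence a.u. to `[0, 1]` x 65535.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = 1000) {
  n <- dim(movie)[3L]
  pages <- lapply(seq_len(n), function(t) {
    pmin(pmax(movie[, , t] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie written by [write_movie_tiff()]
#' @param path TIFF file.
#' @param scale the scale used when writing.
#' @return array height x width x frames.
#' @export
read_movie_tiff <- function(path, scale = 1000) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  arr
}

#' Serialize ROIs to a label image and JSON metadata
#'
#' @param rois list of `roi_mask`.
#' @param field_px field dimensions.
#' @param json_path metadata output (id, kind, cell_type, quality, pixels).
#' @param label_tiff_path optional label-image TIFF (0 = background).
#' @param automated logical flag recorded in the metadata (e.g. bouton
#'   detection standing in for manual annotation).
#' @return `json_path`, invisibly.
#' @export
write_rois_json <- function(rois, field_px, json_path,
                            label_tiff_path = NULL, automated = TRUE) {
  meta <- lapply(rois, function(r) {
    list(id = r$id, kind = r$kind, cell_type = r$cell_type,
         quality = r$quality, automated = automated,
         pixels = unname(apply(r$pixels, 1L, function(p) as.integer(p),
                               simplify = FALSE)))
  })
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(label_tiff_path)) {
    lab <- matrix(0L, field_px[1L], field_px[2L])
    for (r in rois) lab[px_index(r$pixels, field_px[1L])] <- r$id
    tiff::writeTIFF(lab / max(1L, max(lab)), label_tiff_path,
                    bits.per.sample = 16L)
  }
  invisible(json_path)
}

#' Read ROIs back from JSON metadata
#' @param json_path file written by [write_rois_json()].
#' @return list of `roi_mask`.
#' @export
read_rois_json <- function(json_path) {
  meta <- jsonlite::read_json(json_path)
  lapply(meta, function(m) {
    px <- do.call(rbind, lapply(m$pixels, function(p)
      c(row = p[[1L]], col = p[[2L]])))
    roi_mask(m$id, px, kind = m$kind,
             cell_type = m$cell_type %||% "unknown",
             quality = m$quality %||% NA_real_)
  })
}

#' Write the stimulus log as CSV
#'
#' Columns: `onset_frame` (0-based), `size_deg`, `orientation_deg`; phase
#' durations go into a header comment-free sidecar column set
#' (`pre_static_s`, `drift_s`, `post_static_s`, `gap_s`, identical rows).
#' @param stim_log data frame from [generate_stimulus_schedule()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stim_log_csv <- function(stim_log, path) {
  ph <- attr(stim_log, "phase_durations_s")
  out <- cbind(stim_log, pre_static_s = ph[1L], drift_s = ph[2L],
               post_static_s = ph[3L], gap_s = ph[4L])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus log CSV written by [write_stim_log_csv()]
#' @param path CSV path.
#' @return stimulus log data frame with phase durations attached.
#' @export
read_stim_log_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- d[c("onset_frame", "size_deg", "orientation_deg")]
  attr(out, "phase_durations_s") <-
    as.numeric(d[1L, c("pre_static_s", "drift_s", "post_static_s",
                       "gap_s")])
  out
}

#' Write a locomotion trace as CSV (frame, speed_cms)
#' @param speed numeric speed per frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_locomotion_csv <- function(speed, path) {
  utils::write.csv(data.frame(frame = seq_along(speed) - 1L,
                              speed_cms = speed),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a session timeline as CSV
#' @param timeline a [session_timeline()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(data.frame(
    baseline_first = timeline$baseline_frames[1L],
    baseline_end = timeline$baseline_frames[2L],
    injection_frame = timeline$injection_frame,
    post_first = timeline$post_frames[1L],
    post_end = timeline$post_frames[2L],
    analysis_first = timeline$analysis_window[1L],
    analysis_end = timeline$analysis_window[2L]), path,
    row.names = FALSE)
  invisible(path)
}

#' Deterministic MD5 hash of a session configuration
#' @param config a [session_config()].
#' @return character MD5 hash.
#' @export
hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
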