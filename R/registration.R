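# Rigid integer-pixel motion correction and the border-cropping rule.

#' Estimate the rigid integer shift between a frame and a reference
#'
#' Finds the integer displacement `(dy, dx)` within `+/- max_shift_px` that
#' maximizes the cross-correlation with the reference, computed in the
#' Fourier domain over circular shifts. Applying the returned shift to the
#' frame (see [shift_frame()]) best aligns it to the reference. A flat
#' (zero-variance) frame returns a zero shift with a warning; a correlation
#' peak below `conf_threshold` (normalized peak height) is flagged
#' low-confidence in the `"confident"` attribute.
#'
#' @param frame,reference numeric matrices of identical shape.
#' @param max_shift_px maximum allowed displacement magnitude per axis.
#' @param conf_threshold normalized correlation-peak height below which the
#'   estimate is flagged low-confidence.
#' @return integer `c(dy, dx)` with attribute `confident` (logical).
#' @export
estimate_shift <- function(frame, reference, max_shift_px = 15L,
                           conf_threshold = 0.2) {
  stopifnot(all(dim(frame) == dim(reference)), max_shift_px >= 0)
  f <- frame - mean(frame)
  r <- reference - mean(reference)
  if (stats::sd(f) == 0) {
    warning("flat frame: returning zero shift", call. = FALSE)
    return(structure(c(dy = 0L, dx = 0L), confident = FALSE))
  }
  cc <- Re(stats::fft(stats::fft(r) * Conj(stats::fft(f)), inverse = TRUE))
  d <- dim(frame)
  # cc[i, j] corresponds to circular displacement (i-1, j-1) of the frame
  offs_r <- c(0:(d[1L] - 1L)); offs_r[offs_r > d[1L] / 2] <-
    offs_r[offs_r > d[1L] / 2] - d[1L]
  offs_c <- c(0:(d[2L] - 1L)); offs_c[offs_c > d[2L] / 2] <-
    offs_c[offs_c > d[2L] / 2] - d[2L]
  ok_r <- abs(offs_r) <= max_shift_px
  ok_c <- abs(offs_c) <= max_shift_px
  sub <- cc[ok_r, ok_c, drop = FALSE]
  i <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  # inverse FFT in R is unnormalized: divide by N to get the raw
  # cross-products, then by (N-1) sd_f sd_r to get a Pearson r
  peak <- max(sub) / (length(f) * (length(f) - 1) *
                        stats::sd(f) * stats::sd(r))
  structure(c(dy = as.integer(offs_r[ok_r][i[1L]]),
              dx = as.integer(offs_c[ok_c][i[2L]])),
            confident = peak >= conf_threshold)
}

#' Circularly shift a frame by an integer displacement
#'
#' Positive `dy` moves content down, positive `dx` moves it right
#' (wrapping); this is the inverse of the jitter recovered by
#' [estimate_shift()].
#' @param frame numeric matrix.
#' @param dy,dx integer displacements.
#' @return shifted matrix.
#' @export
shift_frame <- function(frame, dy, dx) {
  d <- dim(frame)
  ri <- ((seq_len(d[1L]) - 1L - dy) %% d[1L]) + 1L
  ci <- ((seq_len(d[2L]) - 1L - dx) %% d[2L]) + 1L
  frame[ri, ci, drop = FALSE]
}

#' Register a movie to a reference image
#'
#' Estimates and applies a per-frame integer shift. The reference defaults
#' to the mean image of the post-injection epoch when a timeline is given
#' (pre-injection data are thereby registered to the post period), or to
#' the whole-movie mean otherwise.
#'
#' @param movie numeric array height x width x frames.
#' @param reference reference image; `NULL` to build it from the movie.
#' @param timeline optional [session_timeline()] used to build the
#'   post-epoch mean reference.
#' @param max_shift_px maximum displacement per axis.
#' @return list with `movie` (registered array) and `shifts` (data frame
#'   `frame` (0-based), `dy`, `dx`, `confident`).
#' @export
register_movie <- function(movie, reference = NULL, timeline = NULL,
                           max_shift_px = 15L) {
  n <- dim(movie)[3L]
  if (is.null(reference)) {
    idx <- if (!is.null(timeline)) {
      (timeline$post_frames[1L] + 1L):timeline$post_frames[2L]
    } else {
      seq_len(n)
    }
    idx <- idx[idx <= n]
    reference <- apply(movie[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  out <- movie
  shifts <- data.frame(frame = seq_len(n) - 1L, dy = 0L, dx = 0L,
                       confident = TRUE)
  for (t in seq_len(n)) {
    s <- estimate_shift(movie[, , t], reference, max_shift_px)
    shifts$dy[t] <- s[["dy"]]; shifts$dx[t] <- s[["dx"]]
    shifts$confident[t] <- attr(s, "confident")
    if (s[["dy"]] != 0L || s[["dx"]] != 0L) {
      out[, , t] <- shift_frame(movie[, , t], s[["dy"]], s[["dx"]])
    }
  }
  list(movie = out, shifts = shifts)
}

#' Crop a fixed border from every frame
#'
#' Removes `ceil(border_um / pixel_size_um)` pixels from each side of every
#' frame, so that after rigid registration all retained pixels are present
#' in all frames of both epochs. The default border (20 um) exceeds typical
#' brain motion.
#'
#' @param movie array height x width x frames (or a single matrix).
#' @param border_um border width in microns.
#' @param pixel_size_um microns per pixel.
#' @return cropped array (or matrix).
#' @export
crop_border <- function(movie, border_um = 20, pixel_size_um = 1) {
  b <- as.integer(ceiling(border_um / pixel_size_um))
  if (b == 0L) return(movie)
  d <- dim(movie)
  if (2L * b >= d[1L] || 2L * b >= d[2L]) {
    stop("border of ", b, " px removes the whole field", call. = FALSE)
  }
  ri <- (b + 1L):(d[1L] - b)
  ci <- (b + 1L):(d[2L] - b)
  if (length(d) == 3L) movie[ri, ci, , drop = FALSE]
  else movie[ri, ci, drop = FALSE]
}

#' Apply known per-frame jitter to a movie (test utility)
#'
#' Circularly displaces each frame by the given `(dy, dx)`; registering the
#' jittered movie should recover and undo these shifts.
#' @param movie array height x width x frames.
#' @param shifts integer matrix frames x 2 (`dy`, `dx`).
#' @return jittered movie.
#' @export
jitter_movie <- function(movie, shifts) {
  out <- movie
  for (t in seq_len(dim(movie)[3L])) {
    if (shifts[t, 1L] != 0L || shifts[t, 2L] != 0L) {
      out[, , t] <- shift_frame(movie[, , t], shifts[t, 1L], shifts[t, 2L])
    }
  }
  out
}
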