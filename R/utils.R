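# Internal helpers shared across pipeline stages.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Gauss error function
#' @noRd
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Centered moving average truncated at the edges
#'
#' At each index the mean is taken over the window intersected with the
#' series, so edge values average over fewer points rather than being
#' dropped or padded.
#' @noRd
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Derive a well-separated stage seed from a master seed
#'
#' Linear scramble modulo a prime below 2^31, so that nearby master seeds
#' (or nearby stage indices) give unrelated RNG streams.
#' @noRd
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 100003 + as.numeric(stage) * 7919) %%
               2147483629)
}

#' Convert a duration in seconds to a whole number of frames
#' @noRd
s_to_frames <- function(seconds, frame_rate_hz) {
  as.integer(round(seconds * frame_rate_hz))
}

#' Pixel linear indices for (row, col) matrix coordinates
#' @noRd
px_index <- function(rc, nrow) (rc[, 2L] - 1L) * nrow + rc[, 1L]

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
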