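# Size-tuning quantification: trial response amplitudes, tuning curves,
# difference-of-Gaussians (DoG) fits and the surround-suppression index.

#' Difference-of-Gaussians size-tuning parameters
#'
#' Parameter container for the DoG size-tuning model
#' \deqn{R(s) = R_b + K_e \int_{-s/2}^{s/2} e^{-(2y/a)^2} dy
#'            - K_i \int_{-s/2}^{s/2} e^{-(2y/b)^2} dy}
#' where `s` is stimulus diameter in degrees, `Rb` a baseline response,
#' `Ke`/`Ki` the gains of the excitatory center and inhibitory surround and
#' `a`/`b` their space constants (degrees).
#'
#' @param Rb baseline response.
#' @param Ke,Ki nonnegative excitatory/inhibitory gains.
#' @param a,b positive space constants in degrees; the fit constraint used
#'   throughout is `a <= b` (center narrower than surround).
#' @return an object of class `dog_params`.
#' @export
dog_params <- function(Rb, Ke, Ki, a, b) {
  if (Ke < 0 || Ki < 0) stop("Ke and Ki must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(a, "a")
  stopifnot_scalar_pos(b, "b")
  structure(list(Rb = Rb, Ke = Ke, Ki = Ki, a = a, b = b),
            class = "dog_params")
}

#' Evaluate the difference-of-Gaussians size-tuning model
#'
#' Uses the closed form of the two Gaussian integrals,
#' \deqn{R(s) = R_b + K_e \frac{a\sqrt{\pi}}{2}\,\mathrm{erf}(s/a)
#'            - K_i \frac{b\sqrt{\pi}}{2}\,\mathrm{erf}(s/b),}
#' which equals adaptive quadrature of the integral form to numerical
#' precision (checked in the test suite).
#'
#' @param params a [dog_params()] object.
#' @param s stimulus size(s) in degrees, `>= 0`; vectorized.
#' @return numeric vector of model responses.
#' @export
dog_response <- function(params, s) {
  if (any(s < 0)) stop("stimulus size must be >= 0", call. = FALSE)
  params$Rb +
    params$Ke * (params$a * sqrt(pi) / 2) * erf(s / params$a) -
    params$Ki * (params$b * sqrt(pi) / 2) * erf(s / params$b)
}

#' Summarize a fitted (or exact) DoG curve over a tested size range
#'
#' Finds the preferred size on a fine grid inside `[min(sizes), max(sizes)]`,
#' the fitted response at the largest tested size, and the surround
#' suppression index SSI = (R_pref - R_max) / R_pref.
#' @noRd
dog_summary <- function(params, sizes, grid_step = 0.1) {
  grid <- seq(min(sizes), max(sizes), by = grid_step)
  vals <- dog_response(params, grid)
  i <- which.max(vals)
  r_pref <- vals[i]
  r_max <- dog_response(params, max(sizes))
  ssi <- if (r_pref > 0) (r_pref - r_max) / r_pref else NA_real_
  list(s_pref = grid[i], r_pref = r_pref, r_max = r_max, ssi = ssi,
       ssi_defined = r_pref > 0)
}

#' Trial-by-trial evoked response amplitudes
#'
#' For every ROI and every stimulus trial, takes the maximum dF/F during the
#' 2-second drifting phase as the response amplitude. Trials during which
#' the animal was moving (any non-stationary frame between trial onset and
#' offset) are flagged, not deleted, so downstream averages can exclude
#' them.
#'
#' @param dff numeric matrix of dF/F, frames x ROIs (column names used as
#'   ROI ids when present), or a single numeric vector.
#' @param stim_log stimulus log as returned by
#'   [generate_stimulus_schedule()]: a data frame with `onset_frame`
#'   (0-based), `size_deg`, `orientation_deg`, and phase durations stored in
#'   `attr(, "phase_durations_s")`.
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param stationary logical vector per frame (`TRUE` = stationary), e.g.
#'   from [stationary_mask()]. `NULL` treats all frames as stationary.
#' @return a data frame with one row per ROI x trial: `roi_id`, `trial`,
#'   `size_deg`, `orientation_deg`, `amplitude`, `moving`.
#' @export
trial_responses <- function(dff, stim_log, frame_rate_hz,
                            stationary = NULL) {
  dff <- as.matrix(dff)
  n_frames <- nrow(dff)
  phases <- attr(stim_log, "phase_durations_s")
  if (is.null(phases)) phases <- c(5, 2, 2, 3)
  drift_off <- s_to_frames(phases[[1L]], frame_rate_hz)
  drift_len <- s_to_frames(phases[[2L]], frame_rate_hz)
  trial_len <- s_to_frames(sum(unlist(phases)), frame_rate_hz)
  if (drift_len < 1L) stop("drift phase unresolvable at this frame rate",
                           call. = FALSE)
  roi_ids <- colnames(dff)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(ncol(dff)))
  out <- vector("list", nrow(stim_log))
  for (t in seq_len(nrow(stim_log))) {
    onset <- stim_log$onset_frame[t]           # 0-based
    drift <- (onset + drift_off) + seq_len(drift_len)  # 1-based indices
    if (max(drift) > n_frames) {
      stop("stimulus log extends past the end of the session", call. = FALSE)
    }
    trial_frames <- (onset + 1L):min(onset + trial_len, n_frames)
    moving <- if (is.null(stationary)) FALSE else any(!stationary[trial_frames])
    amp <- apply(dff[drift, , drop = FALSE], 2L, max)
    out[[t]] <- data.frame(
      roi_id = roi_ids, trial = t,
      size_deg = stim_log$size_deg[t],
      orientation_deg = stim_log$orientation_deg[t],
      amplitude = as.numeric(amp), moving = moving,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Mean size-tuning curve from trial responses
#'
#' Averages response amplitudes per stimulus size over non-moving trials,
#' either per ROI (`by_roi = TRUE`) or pooled across all ROIs (the
#' population curve used for the population DoG fit). Trials are restricted
#' to an epoch by onset frame when `epoch_frames` is given.
#'
#' @param responses data frame from [trial_responses()].
#' @param stim_log the stimulus log (needed to map trials to onset frames).
#' @param epoch_frames optional half-open 0-based frame interval
#'   `c(first, end)`; only trials with onset inside it are used.
#' @param by_roi average per ROI (`TRUE`) or across all ROIs (`FALSE`).
#' @return data frame with `roi_id` (or `"population"`), `size_deg`,
#'   `mean_response`, `n_trials`; sizes strictly increasing within ROI.
#' @export
population_size_curve <- function(responses, stim_log, epoch_frames = NULL,
                                  by_roi = FALSE) {
  keep <- !responses$moving
  if (!is.null(epoch_frames)) {
    onset <- stim_log$onset_frame[responses$trial]
    keep <- keep & onset >= epoch_frames[1L] & onset < epoch_frames[2L]
  }
  r <- responses[keep, , drop = FALSE]
  if (nrow(r) == 0L) stop("no retained (non-moving) trials in epoch",
                          call. = FALSE)
  grp <- if (by_roi) interaction(r$roi_id, r$size_deg, drop = TRUE) else
    factor(r$size_deg)
  agg <- aggregate(r["amplitude"],
                   by = if (by_roi) list(roi_id = r$roi_id, size_deg = r$size_deg)
                        else list(size_deg = r$size_deg),
                   FUN = mean)
  n <- aggregate(list(n_trials = r$amplitude),
                 by = if (by_roi) list(roi_id = r$roi_id, size_deg = r$size_deg)
                      else list(size_deg = r$size_deg),
                 FUN = length)
  out <- merge(agg, n)
  if (!by_roi) out$roi_id <- "population"
  names(out)[names(out) == "amplitude"] <- "mean_response"
  ord <- if (by_roi) order(out$roi_id, out$size_deg) else order(out$size_deg)
  out <- out[ord, c("roi_id", "size_deg", "mean_response", "n_trials")]
  rownames(out) <- NULL
  out
}

#' Fit the difference-of-Gaussians model to a size-tuning curve
#'
#' Multi-start bounded nonlinear least squares (sum of squared residuals)
#' with the constraint `a <= b`. Starting points are laid out over
#' log-spaced space constants with small deterministic jitter, so the fit is
#' reproducible given `seed`. The preferred size is located on a 0.1 degree
#' grid within the tested size range; `r_max` is the fitted response at the
#' largest tested size and SSI = (r_pref - r_max)/r_pref.
#'
#' @param sizes tested stimulus sizes (degrees), at least 5 distinct values.
#' @param mean_response mean response per size (same length).
#' @param n_starts number of multi-start least-squares runs (default 20;
#'   the SSE surface is multimodal).
#' @param seed integer seed controlling the start-point jitter.
#' @param bounds named list overriding the default box bounds
#'   (`a` in [1, 120], `b/a` in [1, 20], gains in [0, 50 x data scale]).
#' @return an object of class `dog_fit`: list with `params`
#'   ([dog_params()]), `s_pref`, `r_pref`, `r_max`, `ssi`, `sse`,
#'   `converged`, `ssi_defined`.
#' @export
fit_dog <- function(sizes, mean_response, n_starts = 20L, seed = 1L,
                    bounds = list()) {
  ord <- order(sizes)
  sizes <- as.numeric(sizes[ord]); y <- as.numeric(mean_response[ord])
  if (length(unique(sizes)) < 5L) {
    stop("need at least 5 distinct sizes to fit the DoG model", call. = FALSE)
  }
  scale_y <- max(abs(y), 1e-12)
  b_def <- list(a = c(1, 120), brat = c(1, 20), gain = c(0, 50 * scale_y))
  b_def[names(bounds)] <- bounds
  lower <- c(Rb = -5 * scale_y, Ke = b_def$gain[1], Ki = b_def$gain[1],
             a = b_def$a[1], brat = b_def$brat[1])
  upper <- c(Rb = 5 * scale_y, Ke = b_def$gain[2], Ki = b_def$gain[2],
             a = b_def$a[2], brat = b_def$brat[2])

  sse_fun <- function(p) {
    pr <- dog_params(p[["Rb"]], p[["Ke"]], p[["Ki"]], p[["a"]],
                     p[["a"]] * p[["brat"]])
    sum((y - dog_response(pr, sizes))^2)
  }

  # deterministic lattice of starts over log-spaced (a, b/a), jittered
  n_starts <- max(1L, as.integer(n_starts))
  a0 <- exp(seq(log(max(lower[["a"]], min(sizes) / 4)),
                log(min(upper[["a"]], max(sizes))),
                length.out = ceiling(sqrt(n_starts))))
  r0 <- exp(seq(log(1.2), log(min(upper[["brat"]], 8)),
                length.out = ceiling(n_starts / length(a0))))
  grid <- expand.grid(a = a0, brat = r0)[seq_len(n_starts), , drop = FALSE]

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      ke0 <- abs(max(y) - min(y)) / (grid$a[i] * sqrt(pi) / 2 + 1e-9)
      start <- c(Rb = min(y) * stats::runif(1, 0.8, 1.2),
                 Ke = max(ke0, 1e-6) * stats::runif(1, 0.5, 2),
                 Ki = max(ke0, 1e-6) * stats::runif(1, 0.05, 0.8),
                 a = grid$a[i] * stats::runif(1, 0.9, 1.1),
                 brat = grid$brat[i] * stats::runif(1, 0.9, 1.1))
      start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)
      fit <- tryCatch(
        stats::optim(start, sse_fun, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500L)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
  })
  if (is.null(best)) {
    return(structure(list(params = NULL, converged = FALSE,
                          ssi = NA_real_, ssi_defined = FALSE,
                          sse = NA_real_), class = "dog_fit"))
  }
  p <- best$par
  params <- dog_params(p[["Rb"]], p[["Ke"]], p[["Ki"]], p[["a"]],
                       p[["a"]] * p[["brat"]])
  sm <- dog_summary(params, sizes)
  structure(c(list(params = params, sse = best$value, converged = TRUE),
              sm, list(sizes = sizes, data = y)),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  if (!x$converged) {
    cat("DoG fit: did not converge\n"); return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    "DoG fit: Rb=%.3g Ke=%.3g Ki=%.3g a=%.3g b=%.3g | s_pref=%.1f deg, SSI=%s (SSE=%.3g)\n",
    p$Rb, p$Ke, p$Ki, p$a, p$b, x$s_pref,
    if (x$ssi_defined) sprintf("%.3f", x$ssi) else "undefined", x$sse))
  invisible(x)
}

#' Per-ROI fractional change in response at the preferred stimulus
#'
#' For each ROI responsive in the baseline epoch, computes
#' `(post - pre)/pre` of the mean response at the ROI's baseline-preferred
#' size. Responsiveness defaults to the pre-epoch preferred-size response
#' exceeding `responsive_sd` baseline noise SDs.
#'
#' @param pre,post per-ROI tuning curves from
#'   `population_size_curve(..., by_roi = TRUE)` for the two epochs.
#' @param noise_sd named numeric vector of per-ROI baseline dF/F noise SDs
#'   (names = roi ids); `NULL` disables the responsiveness filter.
#' @param responsive_sd responsiveness criterion in units of baseline SD.
#' @return data frame `roi_id`, `pref_size_deg`, `pre_response`,
#'   `post_response`, `fractional_change`, `responsive`.
#' @export
preferred_response_change <- function(pre, post, noise_sd = NULL,
                                      responsive_sd = 2) {
  ids <- intersect(unique(pre$roi_id), unique(post$roi_id))
  rows <- lapply(ids, function(id) {
    p1 <- pre[pre$roi_id == id, ]
    i <- which.max(p1$mean_response)
    s_pref <- p1$size_deg[i]
    r_pre <- p1$mean_response[i]
    r_post <- post$mean_response[post$roi_id == id &
                                 post$size_deg == s_pref]
    if (length(r_post) != 1L) return(NULL)
    responsive <- if (is.null(noise_sd)) TRUE else
      isTRUE(r_pre > responsive_sd * noise_sd[[id]])
    data.frame(roi_id = id, pref_size_deg = s_pref, pre_response = r_pre,
               post_response = r_post,
               fractional_change = if (r_pre > 0) (r_post - r_pre) / r_pre
                                   else NA_real_,
               responsive = responsive, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
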