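# Cross-session group comparisons and machine-readable reports. The
# statistics themselves are standard (Kruskal-Wallis, ANOVA, Tukey-Kramer
# pairwise correction) and delegate to base R; the module's job is the
# wiring: units of analysis, flags and report structure.

#' Compare a metric across treatment groups
#'
#' Runs the requested omnibus test across groups and, when asked, pairwise
#' comparisons with Tukey-Kramer family-wise correction: `TukeyHSD` on the
#' fitted ANOVA, or Tukey-type contrasts on mean ranks (Nemenyi) after a
#' Kruskal-Wallis test. Two-way layouts take a data frame with columns
#' `value`, `a`, `b` and test both main effects and the interaction.
#'
#' @param samples for one-way tests a named list of numeric vectors (one
#'   per group); for `"anova_2way"` a data frame with columns `value`,
#'   `a`, `b`.
#' @param test one of `"kruskal_wallis"`, `"anova_1way"`, `"anova_2way"`.
#' @param pairwise compute Tukey-Kramer corrected pairwise comparisons?
#' @return list of class `group_result`: `test`, `statistic`, `p_value`
#'   (for 2-way, a named vector with the interaction), `pairwise` (data
#'   frame or `NULL`), `n`, `flag`.
#' @export
compare_groups <- function(samples,
                           test = c("kruskal_wallis", "anova_1way",
                                    "anova_2way"),
                           pairwise = FALSE) {
  test <- match.arg(test)
  if (test == "anova_2way") {
    stopifnot(is.data.frame(samples),
              all(c("value", "a", "b") %in% names(samples)))
    fit <- stats::aov(value ~ a * b, data = transform(
      samples, a = factor(a), b = factor(b)))
    tab <- summary(fit)[[1L]]
    eff <- trimws(rownames(tab))[seq_len(nrow(tab) - 1L)]
    p <- stats::setNames(tab[["Pr(>F)"]][seq_along(eff)], eff)
    stat <- stats::setNames(tab[["F value"]][seq_along(eff)], eff)
    pw <- if (pairwise) as.data.frame(stats::TukeyHSD(fit)$`a:b`) else NULL
    return(structure(list(test = test, statistic = stat, p_value = p,
                          pairwise = pw, n = nrow(samples), flag = NULL),
                     class = "group_result"))
  }
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  value <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), lengths(samples)),
                  levels = names(samples))
  flag <- NULL
  if (length(unique(value)) == 1L) {
    # all observations identical: nothing to test
    return(structure(list(test = test, statistic = 0, p_value = 1,
                          pairwise = NULL, n = lengths(samples),
                          flag = "all values identical"),
                     class = "group_result"))
  }
  if (test == "kruskal_wallis") {
    kt <- stats::kruskal.test(value, group)
    stat <- unname(kt$statistic); p <- kt$p.value
    pw <- if (pairwise) tukey_kramer_ranks(value, group) else NULL
  } else {
    fit <- stats::aov(value ~ group)
    tab <- summary(fit)[[1L]]
    stat <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
    pw <- if (pairwise) {
      d <- as.data.frame(stats::TukeyHSD(fit)$group)
      d$comparison <- rownames(d); rownames(d) <- NULL
      d
    } else NULL
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 pairwise = pw, n = lengths(samples), flag = flag),
            class = "group_result")
}

#' Tukey-Kramer-type pairwise comparisons on mean ranks (Nemenyi)
#' @noRd
tukey_kramer_ranks <- function(value, group) {
  rk <- rank(value)
  n <- length(value)
  k <- nlevels(group)
  ni <- tapply(rk, group, length)
  mi <- tapply(rk, group, mean)
  lv <- levels(group)
  combs <- utils::combn(lv, 2L)
  out <- data.frame(comparison = paste(combs[2L, ], combs[1L, ], sep = "-"),
                    diff = NA_real_, p_adj = NA_real_)
  for (j in seq_len(ncol(combs))) {
    g1 <- combs[1L, j]; g2 <- combs[2L, j]
    se <- sqrt(n * (n + 1) / 24 * (1 / ni[[g1]] + 1 / ni[[g2]]))
    q <- abs(mi[[g2]] - mi[[g1]]) / se
    out$diff[j] <- mi[[g2]] - mi[[g1]]
    out$p_adj[j] <- 1 - stats::ptukey(q * sqrt(2), k, Inf)
  }
  out
}

#' @export
print.group_result <- function(x, ...) {
  p <- paste(format(signif(x$p_value, 3)), collapse = ", ")
  cat(sprintf("%s: statistic = %s, p = %s%s\n", x$test,
              paste(format(signif(x$statistic, 4)), collapse = ", "), p,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Build a machine-readable cross-session report
#'
#' Collects per-session results (as produced by [analyze_session()]),
#' groups them by treatment, compares per-ROI fractional changes across
#' treatments (Kruskal-Wallis with Tukey-Kramer pairwise correction, at
#' ROI level, with session counts reported alongside) and returns a
#' deterministic report object; [write_report()] serializes it to JSON and
#' CSV byte-identically for identical inputs.
#'
#' @param sessions list of per-session result lists; each needs at least
#'   `treatment`, `n_rois`, `roi_fractional_change`,
#'   `population_fractional_change` and optionally `ssi_pre`, `ssi_post`,
#'   `ei_r_baseline`, `ei_r_post`, `config_hash`, `seed`.
#' @return list of class `session_report`.
#' @export
build_report <- function(sessions) {
  stopifnot(length(sessions) >= 1L)
  treat <- vapply(sessions, function(s) s$treatment, character(1))
  per_session <- data.frame(
    session = seq_along(sessions), treatment = treat,
    n_rois = vapply(sessions, function(s) s$n_rois, numeric(1)),
    population_fractional_change =
      vapply(sessions, function(s) s$population_fractional_change,
             numeric(1)),
    ssi_pre = vapply(sessions, function(s) s$ssi_pre %||% NA_real_,
                     numeric(1)),
    ssi_post = vapply(sessions, function(s) s$ssi_post %||% NA_real_,
                      numeric(1)),
    ei_r_baseline = vapply(sessions,
                           function(s) s$ei_r_baseline %||% NA_real_,
                           numeric(1)),
    ei_r_post = vapply(sessions, function(s) s$ei_r_post %||% NA_real_,
                       numeric(1)))
  groups <- split(seq_along(sessions), treat)
  roi_fc <- lapply(groups, function(idx) {
    unlist(lapply(sessions[idx],
                  function(s) s$roi_fractional_change))
  })
  tests <- if (length(groups) >= 2L) {
    list(roi_fractional_change =
           compare_groups(roi_fc, "kruskal_wallis", pairwise = TRUE))
  } else {
    list(skipped = "only one treatment group; between-group tests skipped")
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("capipe")),
    seeds = lapply(sessions, function(s) s$seed %||% NA),
    config_hash = lapply(sessions, function(s) s$config_hash %||% NA))
  structure(list(per_session = per_session, group_tests = tests,
                 roi_fractional_change = roi_fc, provenance = provenance),
            class = "session_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Type-I error calibration of the group comparison under the null
#'
#' Simulates triplets of sessions from identical generators: each session
#' contributes per-ROI fractional changes computed from Poisson spike
#' counts in a baseline and a post window with equal underlying rates (no
#' treatment effect), and the three groups are compared with the
#' Kruskal-Wallis test. Returns the rejection rate at `alpha`, which
#' should match `alpha` for a calibrated test.
#'
#' @param n_reps number of simulated session triplets.
#' @param n_rois ROIs per session.
#' @param lambda_base expected baseline spike count per ROI (window
#'   total).
#' @param window_ratio post/baseline window length ratio.
#' @param alpha nominal level.
#' @param rng_seed seed.
#' @return list with `rejection_rate`, `n_reps`, `alpha`.
#' @export
kw_null_calibration <- function(n_reps = 1000L, n_rois = 20L,
                                lambda_base = 50, window_ratio = 5 / 3,
                                alpha = 0.05, rng_seed = 1L) {
  with_seed(rng_seed, {
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      groups <- lapply(1:3, function(g) {
        base <- stats::rpois(n_rois, lambda_base)
        post <- stats::rpois(n_rois, lambda_base * window_ratio)
        keep <- base > 0
        post[keep] / (base[keep] * window_ratio) - 1
      })
      res <- compare_groups(groups, "kruskal_wallis")
      rej[r] <- res$p_value < alpha
    }
    list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
  })
}

#' Serialize a report to JSON (and optionally CSV)
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report a `session_report` from [build_report()].
#' @param json_path output JSON path.
#' @param csv_path optional path for the per-session CSV table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  gt <- report$group_tests
  tests_json <- lapply(gt, function(t) {
    if (is.character(t)) return(t)
    list(test = t$test, statistic = t$statistic, p_value = t$p_value,
         n = as.list(t$n),
         pairwise = if (!is.null(t$pairwise)) t$pairwise else NULL)
  })
  obj <- list(per_session = report$per_session,
              group_tests = tests_json,
              provenance = report$provenance)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_session, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
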