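# Group comparisons and report building.

perm_test_p <- function(a, b, n_perm = 2000L) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  n <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- sample(pool)
    if (abs(mean(s[1:n]) - mean(s[-(1:n)])) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

test_that("identical groups give a null result, shifted groups reject", {
  r <- compare_groups(list(a = rep(1, 10), b = rep(1, 10)),
                      "kruskal_wallis")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_match(r$flag, "identical")

  set.seed(17)
  a <- stats::rnorm(50); b <- stats::rnorm(50, 2)   # delta = 2 SD
  for (test in c("kruskal_wallis", "anova_1way")) {
    r2 <- compare_groups(list(a = a, b = b), test)
    expect_lt(r2$p_value, 0.001)
  }
  # a permutation oracle agrees on the rejection
  expect_lt(perm_test_p(a, b), 0.001)
})

test_that("pairwise Tukey-Kramer comparisons flag the shifted group only", {
  set.seed(23)
  g <- list(a = stats::rnorm(40), b = stats::rnorm(40, 1.5),
            c = stats::rnorm(40))
  r <- compare_groups(g, "kruskal_wallis", pairwise = TRUE)
  pw <- r$pairwise
  expect_lt(pw$p_adj[pw$comparison == "b-a"], 0.001)
  expect_lt(pw$p_adj[pw$comparison == "c-b"], 0.001)
  expect_gt(pw$p_adj[pw$comparison == "c-a"], 0.05)
  ra <- compare_groups(g, "anova_1way", pairwise = TRUE)
  expect_lt(ra$pairwise$`p adj`[ra$pairwise$comparison == "b-a"], 0.001)
})

test_that("two-way interaction p-values are calibrated under the null", {
  set.seed(41)
  n_reps <- 400L
  rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    d <- data.frame(value = stats::rnorm(40),
                    a = rep(c("x", "y"), 20),
                    b = rep(c("u", "v"), each = 20))
    r <- compare_groups(d, "anova_2way")
    rej[i] <- r$p_value[["a:b"]] < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("reports are structured and byte-identical on re-run", {
  mk <- function(tr, seed) {
    list(treatment = tr, n_rois = 10,
         roi_fractional_change = seq(-0.5, 0.4, 0.1) + seed / 100,
         population_fractional_change = -0.3, ssi_pre = 0.5,
         ssi_post = 0.4, ei_r_baseline = 0.8, ei_r_post = 0.7,
         seed = seed, config_hash = "abc")
  }
  single <- build_report(list(mk("saline", 1)))
  expect_match(single$group_tests$skipped, "one treatment")

  rep3 <- build_report(list(mk("saline", 1), mk("mk801", 2),
                            mk("mk801_muscimol", 3)))
  expect_equal(nrow(rep3$per_session), 3L)
  expect_s3_class(rep3$group_tests$roi_fractional_change, "group_result")

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep3, f1)
  write_report(build_report(list(mk("saline", 1), mk("mk801", 2),
                                 mk("mk801_muscimol", 3))), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
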