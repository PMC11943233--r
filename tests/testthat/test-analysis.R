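toy_trajectory <- function(ce, tofr, dt_s = 60) {
  n <- length(ce)
  data.frame(
    time_s = (seq_len(n) - 1) * dt_s,
    ce_rb = ce,
    tofc = ifelse(is.na(tofr), 3L, 4L),
    tofr = tofr
  )
}

test_that("recovery metrics reproduce the hand-traced toy trajectory", {
  traj <- toy_trajectory(
    ce = c(1.0, 0.5, 0.20, 0.05, 0.02, 0.04, 0.03),
    tofr = c(0.2, 0.5, 0.93, 0.95, 0.96, 0.97, 0.98)
  )
  m <- recovery_metrics(traj, sgx_t0_s = 0, horizon_min = 10)
  expect_identical(m$ce_r, 0.20)
  expect_identical(m$ce_min, 0.02)
  expect_identical(m$ce_max, 0.04)
  expect_equal(m$t_r_min, 2)   # first TOFR >= 0.9 at step 3
  expect_equal(m$t_min_min, 2) # nadir two steps after the crossing
  expect_equal(m$t_max_min, 3)
  expect_true(m$rebound)
  expect_false(m$recur)
})

test_that("monotone decline after recovery yields no rebound and no risk", {
  traj <- toy_trajectory(
    ce = c(1.0, 0.4, 0.2, 0.1, 0.05, 0.025, 0.012),
    tofr = c(0.3, 0.7, 0.92, 0.95, 0.97, 0.98, 0.99)
  )
  m <- recovery_metrics(traj, 0, horizon_min = 10)
  expect_false(m$rebound)
  expect_true(is.na(m$ce_max))
  expect_false(m$recur)
})

test_that("a post-nadir rise above the recovery concentration is flagged", {
  traj <- toy_trajectory(
    ce = c(1.0, 0.5, 0.20, 0.02, 0.01, 0.1, 0.22, 0.15),
    tofr = c(0.2, 0.6, 0.91, 0.95, 0.97, 0.96, 0.93, 0.94)
  )
  m <- recovery_metrics(traj, 0, horizon_min = 10)
  expect_true(m$rebound)
  expect_equal(m$ce_max, 0.22)
  expect_true(m$recur) # 0.22 > 1.1 * 0.20 > Ce_r
})

test_that("never recovering is an analysis error, not a silent result", {
  traj <- toy_trajectory(ce = c(1, 0.9, 0.8), tofr = c(0.1, 0.2, 0.3))
  expect_error(recovery_metrics(traj, 0, horizon_min = 10),
               class = "recurasim_analysis_error")
})

test_that("target concentration averages only over TOFC = 1 ticks", {
  traj <- data.frame(
    time_s = seq(0, 120, by = 12),
    ce_rb = rep(c(0.8, 1.2), length.out = 11),
    tofc = rep(1L, 11), tofr = NA_real_
  )
  expect_equal(target_ce(traj, 0, 120), mean(traj$ce_rb))
  # constant value
  traj$ce_rb <- 1.0
  expect_equal(target_ce(traj, 0, 120), 1.0)
  # masked average: TOFC = 0 ticks are excluded
  traj$ce_rb <- seq(1, 2, length.out = 11)
  traj$tofc <- rep(c(1L, 0L), length.out = 11)
  keep <- traj$tofc == 1
  expect_equal(target_ce(traj, 0, 120), mean(traj$ce_rb[keep]))
  traj$tofc <- 0L
  expect_error(target_ce(traj, 0, 120),
               class = "recurasim_analysis_error")
})

test_that("pearson_r matches closed-form cases and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_error(pearson_r(rep(1, 5), x), "constant")
  expect_error(pearson_r(x, x[1:3]), "equal length")
})

test_that("correlation bands match the printed classification", {
  expect_equal(classify_correlation(0.55), "correlation")
  expect_equal(classify_correlation(-0.39), "weak")
  expect_equal(classify_correlation(0.1), "none")
  expect_equal(classify_correlation(-0.85), "strong")
  # boundaries go to the stronger band
  expect_equal(classify_correlation(0.7), "strong")
  expect_equal(classify_correlation(0.4), "correlation")
  expect_equal(classify_correlation(-0.2), "weak")
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("the classification is exhaustive and mutually exclusive on [-1, 1]", {
  rs <- seq(-1, 1, by = 0.001)
  labels <- vapply(rs, classify_correlation, character(1))
  expect_true(all(labels %in% c("strong", "correlation", "weak", "none")))
  # symmetric in sign
  expect_identical(labels, rev(labels))
})

test_that("group comparison: identical groups give p = 1, separated groups p < 0.001", {
  d <- data.frame(v = rep(c(1, 2, 3), 2))
  g <- rep(c("a", "b"), each = 3)
  cmp <- compare_groups(d, g)
  expect_equal(cmp$p_value, 1)

  set.seed(123)
  d2 <- data.frame(v = c(rnorm(50, 0, 1), rnorm(24, 2, 1)))
  g2 <- rep(c("NA_group", "A"), c(50, 24))
  cmp2 <- compare_groups(d2, g2)
  expect_lt(cmp2$p_value, 0.001)
  expect_setequal(c(cmp2$n_1, cmp2$n_2), c(50, 24))
  # pooled-variance test is the default; Welch differs
  cmp3 <- compare_groups(d2, g2, welch = TRUE)
  expect_false(identical(cmp2$p_value, cmp3$p_value))
  # matches t.test directly
  expect_equal(cmp2$p_value,
               t.test(v ~ g2, data = d2, var.equal = TRUE)$p.value)
  expect_error(compare_groups(d2, rep(c("a", "b"), c(73, 1))),
               class = "recurasim_analysis_error")
})

test_that("cohort summary counts mirror the flags", {
  m <- data.frame(
    t_r_min = rnorm(74, 2, 0.2), ce_r = runif(74, 0.1, 0.5),
    t_min_min = rnorm(74, 6, 1), ce_min = runif(74, 0.001, 0.02),
    t_max_min = rnorm(74, 28, 5), ce_max = runif(74, 0.01, 0.1),
    rebound = c(rep(TRUE, 72), FALSE, FALSE),
    recur = rep(FALSE, 74),
    n_supplements = c(rep(0L, 50), rep(1L, 17), rep(2L, 7)),
    total_sgx_mg_kg = 2 + 0.5 * c(rep(0L, 50), rep(1L, 17), rep(2L, 7))
  )
  m$ce_max[!m$rebound] <- NA
  s <- cohort_summary(m)
  expect_equal(unname(s$counts["n"]), 74)
  expect_equal(unname(s$counts["rebound"]), 72)
  expect_equal(unname(s$counts["recur"]), 0)
  expect_equal(unname(s$counts["supplemented"]), 24)
  ce_max_row <- s$stats[s$stats$variable == "ce_max", ]
  expect_equal(ce_max_row$n, 72)
  # single patient: zero SDs, no error
  s1 <- cohort_summary(m[1, ])
  expect_true(all(s1$stats$sd == 0))
})
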