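#' Post-reversal recovery metrics
#'
#' Extracts the endpoint metrics from a trajectory: the effect-site
#' concentration at the first TOFR >= 0.9 observation (`ce_r`), the
#' post-recovery nadir (`ce_min` at `t_min_min` minutes after the
#' crossing), the rebound peak after the nadir (`ce_max` at `t_max_min`
#' minutes after the crossing, present only when the post-nadir rise
#' exceeds a relative detection tolerance), and the recurarization flag
#' (`ce_max > ce_r`).
#'
#' @param traj Trajectory data frame (`time_s`, `ce_rb`, `tofc`, `tofr`);
#'   any grid spacing is accepted.
#' @param sgx_t0_s Time of the initial sugammadex bolus, seconds.
#' @param horizon_min Analysis window after the bolus, minutes
#'   (default 60).
#' @param rebound_tol Relative rise over the nadir required to declare a
#'   rebound (default 1%), so numerical ripple is not counted as a
#'   second increase.
#' @return One-row data frame: `t_r_min`, `ce_r`, `t_min_min`, `ce_min`,
#'   `t_max_min`, `ce_max`, `rebound`, `recur`.
#' @export
recovery_metrics <- function(traj, sgx_t0_s, horizon_min = 60,
                             rebound_tol = 0.01) {
  w <- traj[traj$time_s >= sgx_t0_s &
              traj$time_s <= sgx_t0_s + horizon_min * 60, , drop = FALSE]
  if (!nrow(w)) stop("trajectory does not cover the analysis window",
                     call. = FALSE)
  rec <- which(w$tofc == 4 & !is.na(w$tofr) & w$tofr >= 0.9)
  if (!length(rec)) {
    stop(errorCondition("not recovered: TOFR never reached 0.9 in window",
                        class = c("recurasim_analysis_error", "error",
                                  "condition")))
  }
  i_r <- rec[1]
  t_r <- w$time_s[i_r]
  ce_r <- w$ce_rb[i_r]
  after <- w[i_r:nrow(w), , drop = FALSE]
  i_min <- which.min(after$ce_rb)
  ce_min <- after$ce_rb[i_min]
  t_min <- after$time_s[i_min]
  ce_max <- NA_real_
  t_max <- NA_real_
  rebound <- FALSE
  if (i_min < nrow(after)) {
    post <- after[(i_min + 1):nrow(after), , drop = FALSE]
    i_max <- which.max(post$ce_rb)
    if (post$ce_rb[i_max] > ce_min * (1 + rebound_tol)) {
      rebound <- TRUE
      ce_max <- post$ce_rb[i_max]
      t_max <- post$time_s[i_max]
    }
  }
  data.frame(
    t_r_min = (t_r - sgx_t0_s) / 60,
    ce_r = ce_r,
    t_min_min = (t_min - t_r) / 60,
    ce_min = ce_min,
    t_max_min = (t_max - t_r) / 60,
    ce_max = ce_max,
    rebound = rebound,
    recur = isTRUE(!is.na(ce_max) && ce_max > ce_r)
  )
}

#' Intraoperative target effect-site concentration
#'
#' Time-average of the rocuronium effect-site concentration over a
#' steady maintenance window, restricted to observation ticks at
#' TOFC = 1 (the maintenance target).
#'
#' @param traj Trajectory data frame.
#' @param window_start_s,window_end_s Averaging window, seconds.
#' @return Mean `ce_rb` over TOFC = 1 ticks in the window (ug/mL).
#' @export
target_ce <- function(traj, window_start_s, window_end_s) {
  w <- traj[traj$time_s >= window_start_s & traj$time_s <= window_end_s &
              traj$tofc == 1, , drop = FALSE]
  if (!nrow(w)) {
    stop(errorCondition("no TOFC = 1 ticks in the requested window",
                        class = c("recurasim_analysis_error", "error",
                                  "condition")))
  }
  mean(w$ce_rb)
}

#' Pearson correlation with input validation
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlation strength classification
#'
#' Bands on |r|: \[0.7, 1\] strong correlation, \[0.4, 0.7\) correlation,
#' \[0.2, 0.4\) weak correlation, \[0, 0.2\) no correlation. The printed
#' band limits overlap at 0.2/0.4/0.7; boundary values are assigned to
#' the stronger label so the classification is deterministic, exhaustive
#' and mutually exclusive.
#'
#' @param r Correlation coefficient, |r| <= 1.
#' @return One of `"strong"`, `"correlation"`, `"weak"`, `"none"`.
#' @export
classify_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1) {
    stop("`r` must be a correlation coefficient in [-1, 1]", call. = FALSE)
  }
  a <- abs(r)
  if (a >= 0.7) "strong"
  else if (a >= 0.4) "correlation"
  else if (a >= 0.2) "weak"
  else "none"
}

#' Two-group comparison of patient metrics
#'
#' Per-variable mean +/- SD in each group and a two-sided two-sample
#' t-test p-value (pooled variance by default, Welch optionally), as used
#' to compare patients who needed supplemental sugammadex against those
#' who did not.
#'
#' @param data Data frame of per-patient variables.
#' @param group Logical or two-level vector splitting the rows.
#' @param vars Variables to compare (default: all numeric columns).
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   pooled-variance Student test.
#' @return Data frame: variable, per-group n/mean/sd, `p_value`.
#' @export
compare_groups <- function(data, group, vars = NULL, welch = FALSE) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("`group` must have exactly two levels",
                            call. = FALSE)
  if (min(table(g)) < 2) {
    stop(errorCondition("each group needs at least 2 observations",
                        class = c("recurasim_analysis_error", "error",
                                  "condition")))
  }
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x1 <- data[[v]][g == lv[1]]
    x2 <- data[[v]][g == lv[2]]
    p <- if (stats::sd(x1) == 0 && stats::sd(x2) == 0 &&
             mean(x1) == mean(x2)) {
      1
    } else {
      stats::t.test(x1, x2, var.equal = !welch)$p.value
    }
    data.frame(
      variable = v,
      n_1 = length(x1), mean_1 = mean(x1), sd_1 = stats::sd(x1),
      n_2 = length(x2), mean_2 = mean(x2), sd_2 = stats::sd(x2),
      p_value = p
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}

#' Cohort summary block
#'
#' Mean, SD, minimum and maximum of each recovery metric plus the four
#' protocol counts: cohort size, patients with a detected rebound,
#' patients flagged for recurarization risk, and patients who needed
#' supplemental sugammadex.
#'
#' @param metrics Data frame of per-patient [recovery_metrics()] rows
#'   (with `total_sgx_mg_kg` if available).
#' @return List with `stats` (data frame) and `counts` (named integers).
#' @export
cohort_summary <- function(metrics) {
  if (!nrow(metrics)) stop("`metrics` is empty", call. = FALSE)
  num_vars <- intersect(
    c("t_r_min", "ce_r", "t_min_min", "ce_min", "t_max_min", "ce_max",
      "target_ce", "recovery_obs_min", "total_sgx_mg_kg", "rb_dose_mg"),
    names(metrics)
  )
  stats_df <- do.call(rbind, lapply(num_vars, function(v) {
    x <- metrics[[v]][!is.na(metrics[[v]])]
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               min = min(x), max = max(x))
  }))
  counts <- c(
    n = nrow(metrics),
    rebound = sum(metrics$rebound, na.rm = TRUE),
    recur = sum(metrics$recur, na.rm = TRUE),
    supplemented = if ("n_supplements" %in% names(metrics)) {
      sum(metrics$n_supplements > 0, na.rm = TRUE)
    } else {
      NA_integer_
    }
  )
  list(stats = stats_df, counts = counts)
}
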