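#' End-to-end cohort simulation pipeline
#'
#' Generates a synthetic cohort, runs the full protocol (induction,
#' TOFC = 1 maintenance for the sampled operation time, stepped
#' sugammadex reversal, post-reversal follow-up) for every patient,
#' extracts recovery metrics, and assembles the cohort-level analyses:
#' summary block, correlations of age / renal function / intraoperative
#' target concentration with the recovery threshold concentration, and
#' the supplemented-vs-not group comparison.
#'
#' A per-patient failure (e.g. protocol failure in an extreme draw) is
#' recorded and the pipeline continues; it stops only if every patient
#' fails.
#'
#' @param n Cohort size (>= 1).
#' @param seed RNG seed; the run is fully reproducible from it.
#' @param base_params Population parameter set.
#' @param cohort_cfg A [cohort_config()].
#' @param ctrl A [controller_config()].
#' @param horizon_min Post-reversal analysis horizon, minutes.
#' @param outdir Optional output directory; when given, writes
#'   `cohort.csv`, `metrics.csv`, `summary.txt`, `correlations.csv`,
#'   `comparison.csv` and (optionally) per-patient trajectories and
#'   dosing records.
#' @param write_trajectories Also write one trajectory and dosing-record
#'   CSV per patient (off by default).
#' @param rtol,atol Solver tolerances.
#' @param quiet Suppress per-patient progress messages.
#' @return List: `cohort`, `metrics` (one row per patient), `summary`,
#'   `correlations`, `comparison`, `warnings_n`, `errors` (named list of
#'   per-patient failures), `results` (per-patient protocol outputs,
#'   trajectories dropped unless `write_trajectories`).
#' @export
run_pipeline <- function(n = 74, seed = 1,
                         base_params = default_pkpd_parameters(),
                         cohort_cfg = cohort_config(),
                         ctrl = controller_config(),
                         horizon_min = 60,
                         outdir = NULL,
                         write_trajectories = FALSE,
                         rtol = 1e-8, atol = 1e-10,
                         quiet = TRUE) {
  if (!is.numeric(n) || n < 1) {
    stop(errorCondition("`n` must be >= 1",
                        class = c("recurasim_config_error", "error",
                                  "condition")))
  }
  cohort <- generate_cohort(n, seed, cohort_cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
  }
  metrics_rows <- list()
  errors <- list()
  warnings_n <- 0L
  for (i in seq_len(n)) {
    pat <- cohort[i, , drop = FALSE]
    res <- tryCatch(
      run_protocol(pat, base_params = base_params, cfg = ctrl,
                   horizon_min = horizon_min, rtol = rtol, atol = atol),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[as.character(pat$id)]] <- conditionMessage(res)
      if (!quiet) message("patient ", pat$id, " failed: ",
                          conditionMessage(res))
      next
    }
    warnings_n <- warnings_n + nrow(res$warnings)
    m <- cbind(data.frame(id = pat$id, sex = pat$sex, age_y = pat$age_y,
                          weight_kg = pat$weight_kg,
                          eccr_ml_min = pat$eccr_ml_min),
               res$metrics)
    metrics_rows[[length(metrics_rows) + 1L]] <- m
    if (!is.null(outdir) && write_trajectories) {
      pdir <- file.path(outdir, "patients")
      dir.create(pdir, showWarnings = FALSE)
      write_trajectory(res$trajectory,
                       file.path(pdir, sprintf("trajectory_%03d.csv", pat$id)))
      write_dosing_record(res$record,
                          file.path(pdir, sprintf("record_%03d.csv", pat$id)))
    }
    if (!quiet) message("patient ", pat$id, " done")
  }
  if (!length(metrics_rows)) {
    stop("all patients failed: ",
         paste(unlist(errors), collapse = "; "), call. = FALSE)
  }
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL
  summary <- cohort_summary(metrics)

  correlations <- NULL
  if (nrow(metrics) >= 3 && stats::sd(metrics$ce_r) > 0) {
    correlations <- do.call(rbind, lapply(
      c("age_y", "eccr_ml_min", "target_ce"),
      function(v) {
        r <- pearson_r(metrics[[v]], metrics$ce_r)
        data.frame(variable = v, r = r, label = classify_correlation(r))
      }
    ))
  }

  comparison <- NULL
  supplemented <- metrics$n_supplements > 0
  if (length(unique(supplemented)) == 2 && min(table(supplemented)) >= 2) {
    comparison <- compare_groups(
      metrics, ifelse(supplemented, "A", "NA_group"),
      vars = c("age_y", "weight_kg", "eccr_ml_min", "rb_dose_mg",
               "target_ce", "ce_r")
    )
  }

  if (!is.null(outdir)) {
    write_metrics(metrics, file.path(outdir, "metrics.csv"))
    writeLines(format_summary(summary), file.path(outdir, "summary.txt"))
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                       row.names = FALSE)
    }
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                       row.names = FALSE)
    }
  }
  list(cohort = cohort, metrics = metrics, summary = summary,
       correlations = correlations, comparison = comparison,
       warnings_n = warnings_n, errors = errors)
}
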