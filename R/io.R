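#' Device-dialect dosing record I/O
#'
#' The automated delivery device logs drug administration every 12 s as
#' CSV. The dialect used here has columns `time_s`, `rb_ug_per_min`
#' (mean rocuronium administration rate over the 12-s interval; boluses
#' appear as the equivalent rate over the interval in which they were
#' given), `sgx_bolus_ug` (sugammadex bolus at the interval start) and
#' the optional observation columns `tofc`, `tofr`. It is declared and
#' validated here, not claimed to be byte-compatible with any real
#' device.
#'
#' `read_dosing_record()` validates the cadence (exactly `dt_s` between
#' rows), strictly increasing times, and non-negative doses, and returns
#' the canonical event list: one `infusion_rate` event per rate change
#' and one `bolus` event per positive sugammadex entry. Writing the
#' record of a controller run and reading it back yields the file's
#' canonical events exactly (bit-exact CSV round trip).
#'
#' @param record Data frame with the columns above (a controller run's
#'   `record`).
#' @param path CSV path.
#' @param dt_s Expected cadence, seconds.
#' @return `read_dosing_record()`: a [dose_events()] data frame.
#' @export
write_dosing_record <- function(record, path) {
  req <- c("time_s", "rb_ug_per_min", "sgx_bolus_ug")
  if (!all(req %in% names(record))) {
    stop("record must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cols <- c(req, intersect(c("tofc", "tofr"), names(record)))
  utils::write.csv(record[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosing_record
#' @export
read_dosing_record <- function(path, dt_s = 12) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "rb_ug_per_min", "sgx_bolus_ug")
  missing <- setdiff(req, names(rec))
  if (length(missing)) {
    stop(parse_error("missing column(s): ",
                     paste(missing, collapse = ", ")))
  }
  if (!nrow(rec)) return(dose_events(numeric(), character(), character(),
                                     numeric()))
  for (nm in req) {
    bad <- which(!is.finite(rec[[nm]]))
    if (length(bad)) {
      stop(parse_error("malformed value in `", nm, "` at row ", bad[1]))
    }
  }
  gaps <- which(abs(diff(rec$time_s) - dt_s) > 1e-9)
  if (length(gaps)) {
    stop(parse_error("broken ", dt_s, "-s cadence at row ", gaps[1] + 1,
                     " (time ", rec$time_s[gaps[1] + 1], " s)"))
  }
  neg <- which(rec$rb_ug_per_min < 0 | rec$sgx_bolus_ug < 0)
  if (length(neg)) {
    stop(parse_error("negative dose at row ", neg[1]))
  }
  record_to_events(rec)
}

parse_error <- function(...) {
  errorCondition(paste0(...),
                 class = c("recurasim_parse_error", "error", "condition"))
}

# Canonical events of a dosing record: a rate event wherever the
# rocuronium column changes (including the first row), a bolus event for
# every positive sugammadex entry.
record_to_events <- function(rec) {
  changed <- c(TRUE, diff(rec$rb_ug_per_min) != 0)
  ev_rate <- data.frame(
    time_s = rec$time_s[changed],
    drug = "rb", kind = "infusion_rate",
    magnitude = rec$rb_ug_per_min[changed]
  )
  has_sgx <- rec$sgx_bolus_ug > 0
  ev <- ev_rate
  if (any(has_sgx)) {
    ev <- rbind(ev, data.frame(
      time_s = rec$time_s[has_sgx],
      drug = "sgx", kind = "bolus",
      magnitude = rec$sgx_bolus_ug[has_sgx]
    ))
  }
  dose_events(ev$time_s, ev$drug, ev$kind, ev$magnitude)
}

#' Write per-patient metrics to CSV
#'
#' @param metrics Data frame of per-patient metrics.
#' @param path CSV path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Format the cohort summary as text
#'
#' Markdown-ish block mirroring the clinical results layout: counts
#' first, then one line per metric as mean +/- SD (range).
#'
#' @param summary Output of [cohort_summary()].
#' @return Character vector of lines.
#' @export
format_summary <- function(summary) {
  cnt <- summary$counts
  lines <- c(
    "# Cohort summary",
    "",
    sprintf("Patients: %d", cnt[["n"]]),
    sprintf("Post-nadir rebound detected: %d", cnt[["rebound"]]),
    sprintf("Recurarization risk (Ce_max > Ce_r): %d", cnt[["recur"]]),
    sprintf("Needed supplemental sugammadex: %s",
            ifelse(is.na(cnt[["supplemented"]]), "NA",
                   cnt[["supplemented"]])),
    ""
  )
  st <- summary$stats
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf(
      "%-18s %8.3f +/- %.3f  (range %.3f-%.3f, n = %d)",
      st$variable[i], st$mean[i], st$sd[i], st$min[i], st$max[i], st$n[i]
    ))
  }
  lines
}
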