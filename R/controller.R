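#' Closed-loop controller configuration
#'
#' Protocol constants of the automated rocuronium loop and the manual
#' sugammadex reversal, plus the tunables of the rate-adjustment rule.
#' Dose scalars follow the protocol: rocuronium per kg *ideal* body
#' weight, sugammadex per kg *actual* body weight. All timers are
#' quantized to the TOF interval (12 s): TOF is only observable at ticks.
#'
#' The device's internal TOFC = 1 adjustment law is not public; the rule
#' implemented is a bounded step-rate controller: observe the TOF count
#' every tick, decrease the infusion rate one step at TOFC = 0, hold at
#' TOFC = 1, increase one step at TOFC >= 2. The infusion starts at
#' `maintenance_start_rate` the first time a twitch reappears after the
#' induction bolus.
#'
#' @param induction_mg_kg Induction bolus, mg/kg IBW.
#' @param rescue_mg_kg Additional bolus if TOFC has not reached 0 one
#'   minute after induction, mg/kg IBW.
#' @param rescue_check_s Time after induction at which the TOF count is
#'   inspected.
#' @param fallback_rate Continuous-dosing fallback rate, ug/kg IBW/min,
#'   started if TOFC = 0 is still not reached `fallback_delay_s` after the
#'   rescue bolus.
#' @param fallback_delay_s See above.
#' @param tof_interval_s TOF stimulation cadence (12 s).
#' @param target_tofc Maintenance target TOF count.
#' @param warn_no_block_s Warn if TOFC = 0 is not reached after this long
#'   on continuous dosing (12 min).
#' @param warn_high_tofc_s Warn if TOFC >= 3 is sustained this long
#'   (5 min).
#' @param rate_step_up,rate_step_down Adjustment steps, ug/kg IBW/min per
#'   tick.
#' @param rate_max Upper bound of the infusion rate, ug/kg IBW/min.
#' @param maintenance_start_rate Initial maintenance rate, ug/kg IBW/min.
#' @param sgx_initial_mg_kg Initial sugammadex bolus, mg/kg actual weight.
#' @param sgx_supplement_mg_kg Supplemental bolus, mg/kg actual weight.
#' @param sgx_check_s First supplement check (3 min after the initial
#'   bolus).
#' @param sgx_supplement_interval_s Interval between further supplements
#'   (1 min).
#' @param tofr_target Recovery threshold TOF ratio (0.9).
#' @param sgx_delay_s Delay between stopping rocuronium and the manual
#'   sugammadex bolus.
#' @param reversal_cap_s Give up (protocol failure) if the TOF ratio has
#'   not recovered this long after the initial bolus.
#' @return A `controller_config` list.
#' @export
controller_config <- function(induction_mg_kg = 0.6,
                              rescue_mg_kg = 0.3,
                              rescue_check_s = 60,
                              fallback_rate = 7,
                              fallback_delay_s = 180,
                              tof_interval_s = 12,
                              target_tofc = 1,
                              warn_no_block_s = 720,
                              warn_high_tofc_s = 300,
                              rate_step_up = 0.15,
                              rate_step_down = 0.075,
                              rate_max = 30,
                              maintenance_start_rate = 7,
                              sgx_initial_mg_kg = 2,
                              sgx_supplement_mg_kg = 0.5,
                              sgx_check_s = 180,
                              sgx_supplement_interval_s = 60,
                              tofr_target = 0.9,
                              sgx_delay_s = 0,
                              reversal_cap_s = 1800) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  stopifnot(all(num), all(unlist(cfg) >= 0), cfg$tof_interval_s > 0)
  for (nm in c("rescue_check_s", "fallback_delay_s", "sgx_check_s",
               "sgx_supplement_interval_s", "warn_no_block_s",
               "warn_high_tofc_s")) {
    if (cfg[[nm]] %% cfg$tof_interval_s != 0) {
      stop("`", nm, "` must be a multiple of the TOF interval",
           call. = FALSE)
    }
  }
  class(cfg) <- "controller_config"
  cfg
}

# --- internal dosing-record assembly -----------------------------------

ctl_log_new <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$warnings <- list()
  env
}

ctl_log_row <- function(log, time_s, rb_rate, rb_bolus, sgx_bolus,
                        tofc, tofr, dt_s) {
  log$rows[[length(log$rows) + 1L]] <- data.frame(
    time_s = time_s,
    rb_ug_per_min = rb_rate + rb_bolus * 60 / dt_s,
    sgx_bolus_ug = sgx_bolus,
    tofc = tofc, tofr = tofr
  )
}

ctl_warn <- function(log, time_s, type) {
  log$warnings[[length(log$warnings) + 1L]] <-
    data.frame(time_s = time_s, type = type)
}

ctl_log_collect <- function(log) {
  list(
    record = if (length(log$rows)) do.call(rbind, log$rows) else
      data.frame(time_s = numeric(), rb_ug_per_min = numeric(),
                 sgx_bolus_ug = numeric(), tofc = integer(),
                 tofr = numeric()),
    warnings = if (length(log$warnings)) do.call(rbind, log$warnings) else
      data.frame(time_s = numeric(), type = character())
  )
}

#' Sustained high TOF count warning rule
#'
#' Scans a TOF-count observation stream (fixed cadence) and returns the
#' times at which a warning fires: one warning each time TOFC >= 3 has
#' been sustained for `sustain_s`, re-armed only after the condition
#' clears.
#'
#' @param tofc Integer vector of TOF counts observed every `dt_s`.
#' @param dt_s Observation cadence, seconds.
#' @param sustain_s Sustain time that triggers the warning (default
#'   5 min).
#' @param time0_s Time of the first observation.
#' @return Numeric vector of warning times (seconds).
#' @export
high_tofc_warnings <- function(tofc, dt_s = 12, sustain_s = 300,
                               time0_s = 0) {
  run <- 0
  out <- numeric()
  armed <- TRUE
  for (i in seq_along(tofc)) {
    if (tofc[i] >= 3) {
      run <- run + 1
      # sustained for sustain_s: (run - 1) intervals since onset
      if (armed && (run - 1) * dt_s >= sustain_s) {
        out <- c(out, time0_s + (i - 1) * dt_s)
        armed <- FALSE
      }
    } else {
      run <- 0
      armed <- TRUE
    }
  }
  out
}

# --- protocol phases ----------------------------------------------------

#' Anesthesia induction phase
#'
#' Administers the induction bolus (0.6 mg/kg IBW), inspects the TOF
#' count one minute later and gives the rescue bolus (0.3 mg/kg IBW) if
#' any twitch remains; if complete block is still not reached three
#' minutes after the rescue dose, starts the continuous fallback infusion
#' (7 ug/kg IBW/min) and hands over to maintenance after one further
#' tick. The phase otherwise ends at the first TOFC = 0 observation.
#'
#' @param sim A live simulation handle ([new_sim()]).
#' @param patient A [patient_covariates()] object (or cohort row).
#' @param cfg A [controller_config()].
#' @return Fragment list: `record`, `warnings`, `events` bookkeeping,
#'   `end_time_s`, `rescue_given`, `fallback_started_s`,
#'   `blocked` (whether TOFC = 0 was observed).
#' @export
run_induction <- function(sim, patient, cfg = controller_config()) {
  patient <- as_patient(patient)
  ibw <- ideal_body_weight(patient$height_cm, patient$sex)
  dt <- cfg$tof_interval_s
  log <- ctl_log_new()
  t_start <- sim_time(sim)
  rescue_at <- NA_real_
  fallback_at <- NA_real_
  rate <- 0
  blocked <- FALSE
  repeat {
    t <- sim_time(sim)
    obs <- sim_observe(sim)
    el <- t - t_start
    rb_bolus <- 0
    if (el == 0) {
      rb_bolus <- cfg$induction_mg_kg * ibw * 1000
      sim_bolus(sim, "rb", rb_bolus)
    }
    if (obs$tofc == 0) blocked <- TRUE
    if (blocked) {
      ctl_log_row(log, t, rate, rb_bolus, 0, obs$tofc, obs$tofr, dt)
      sim_advance(sim, dt)
      break
    }
    if (el == cfg$rescue_check_s && obs$tofc > 0) {
      rb_bolus <- rb_bolus + cfg$rescue_mg_kg * ibw * 1000
      sim_bolus(sim, "rb", cfg$rescue_mg_kg * ibw * 1000)
      rescue_at <- t
    }
    if (!is.na(rescue_at) && is.na(fallback_at) &&
        el == (rescue_at - t_start) + cfg$fallback_delay_s) {
      rate <- cfg$fallback_rate * ibw
      sim_set_rate(sim, "rb", rate)
      fallback_at <- t
    }
    ctl_log_row(log, t, rate, rb_bolus, 0, obs$tofc, obs$tofr, dt)
    sim_advance(sim, dt)
    # one tick after the fallback started, hand over to auto-adjustment
    if (!is.na(fallback_at) && sim_time(sim) >= fallback_at + dt) break
  }
  c(ctl_log_collect(log),
    list(end_time_s = sim_time(sim), rescue_given = !is.na(rescue_at),
         fallback_started_s = fallback_at, blocked = blocked,
         rate_ug_min = rate))
}

#' Maintenance phase: TOFC = 1 closed loop
#'
#' Runs the step-rate adjustment rule for `duration_s`: the infusion
#' starts at the configured initial rate when the first twitch reappears
#' (or continues from the induction fallback rate), then moves one step
#' down / hold / up per tick for TOFC 0 / 1 / >= 2. Emits the two printed
#' device warnings: no block after 12 min of continuous dosing, and
#' TOFC >= 3 sustained for 5 min.
#'
#' @param sim A live simulation handle.
#' @param patient Patient covariates (or cohort row).
#' @param duration_s Length of the maintenance phase, seconds.
#' @param cfg A [controller_config()].
#' @param start_rate_ug_min Absolute rate carried over from induction
#'   (0 unless the fallback path was taken).
#' @return Fragment list: `record`, `warnings`, `end_time_s`,
#'   `rate_ug_min` (final rate).
#' @export
run_maintenance <- function(sim, patient, duration_s,
                            cfg = controller_config(),
                            start_rate_ug_min = 0) {
  patient <- as_patient(patient)
  ibw <- ideal_body_weight(patient$height_cm, patient$sex)
  dt <- cfg$tof_interval_s
  log <- ctl_log_new()
  t_start <- sim_time(sim)
  rate <- start_rate_ug_min
  started <- rate > 0
  dosing_since <- if (started) t_start else NA_real_
  seen_block <- FALSE
  no_block_warned <- FALSE
  tofc_seq <- integer()
  times_seq <- numeric()
  while (sim_time(sim) - t_start < duration_s) {
    t <- sim_time(sim)
    obs <- sim_observe(sim)
    tofc_seq <- c(tofc_seq, obs$tofc)
    times_seq <- c(times_seq, t)
    if (obs$tofc == 0) seen_block <- TRUE
    new_rate <- rate
    if (!started) {
      if (obs$tofc >= 1) {
        new_rate <- cfg$maintenance_start_rate * ibw
        started <- TRUE
        dosing_since <- t
      }
    } else if (obs$tofc == 0) {
      new_rate <- max(0, rate - cfg$rate_step_down * ibw)
    } else if (obs$tofc >= 2) {
      new_rate <- min(cfg$rate_max * ibw, rate + cfg$rate_step_up * ibw)
    }
    if (new_rate != rate) {
      rate <- new_rate
      sim_set_rate(sim, "rb", rate)
    }
    if (!no_block_warned && !seen_block && !is.na(dosing_since) &&
        t - dosing_since >= cfg$warn_no_block_s) {
      ctl_warn(log, t, "no_block_12min")
      no_block_warned <- TRUE
    }
    ctl_log_row(log, t, rate, 0, 0, obs$tofc, obs$tofr, dt)
    sim_advance(sim, dt)
  }
  out <- ctl_log_collect(log)
  warn_t <- high_tofc_warnings(tofc_seq, dt, cfg$warn_high_tofc_s,
                               time0_s = times_seq[1])
  for (w in warn_t) ctl_warn(log, w, "high_tofc_5min")
  out$warnings <- ctl_log_collect(log)$warnings
  c(out, list(end_time_s = sim_time(sim), rate_ug_min = rate))
}

#' Reversal phase: stepped sugammadex protocol
#'
#' Stops the rocuronium infusion, gives the initial sugammadex bolus
#' (2 mg/kg actual weight), and while the TOF ratio has not reached the
#' recovery threshold gives 0.5 mg/kg supplements at 3 min and every
#' minute thereafter. No dose is given at or after the first
#' TOFR >= 0.9 observation. The simulation is then advanced dose-free to
#' the end of the analysis horizon so the post-recovery rebound of the
#' effect-site concentration is on the record.
#'
#' @param sim A live simulation handle.
#' @param patient Patient covariates (or cohort row).
#' @param cfg A [controller_config()].
#' @param horizon_min Dose-free follow-up after the initial bolus,
#'   minutes.
#' @return Fragment list: `record`, `warnings`, `sgx_t0_s`,
#'   `recovery_s` (from the bolus to the first TOFR >= 0.9 observation),
#'   `total_sgx_mg_kg`, `n_supplements`, `end_time_s`.
#' @export
run_reversal <- function(sim, patient, cfg = controller_config(),
                         horizon_min = 60) {
  patient <- as_patient(patient)
  wt <- patient$weight_kg
  dt <- cfg$tof_interval_s
  log <- ctl_log_new()
  sim_set_rate(sim, "rb", 0)
  if (cfg$sgx_delay_s > 0) {
    n_delay <- ceiling(cfg$sgx_delay_s / dt)
    for (i in seq_len(n_delay)) {
      obs <- sim_observe(sim)
      ctl_log_row(log, sim_time(sim), 0, 0, 0, obs$tofc, obs$tofr, dt)
      sim_advance(sim, dt)
    }
  }
  t0 <- sim_time(sim)
  n_supp <- 0L
  recovery_s <- NA_real_
  end_s <- t0 + horizon_min * 60
  repeat {
    t <- sim_time(sim)
    el <- t - t0
    obs <- sim_observe(sim)
    recovered_now <- obs$tofc == 4 && !is.na(obs$tofr) &&
      obs$tofr >= cfg$tofr_target
    if (is.na(recovery_s) && recovered_now) recovery_s <- el
    sgx_bolus <- 0
    if (el == 0) {
      sgx_bolus <- cfg$sgx_initial_mg_kg * wt * 1000
      sim_bolus(sim, "sgx", sgx_bolus)
    } else if (is.na(recovery_s) && el >= cfg$sgx_check_s &&
               (el - cfg$sgx_check_s) %% cfg$sgx_supplement_interval_s == 0) {
      sgx_bolus <- cfg$sgx_supplement_mg_kg * wt * 1000
      sim_bolus(sim, "sgx", sgx_bolus)
      n_supp <- n_supp + 1L
    }
    ctl_log_row(log, t, 0, 0, sgx_bolus, obs$tofc, obs$tofr, dt)
    if (is.na(recovery_s) && el >= cfg$reversal_cap_s) {
      stop(errorCondition(
        sprintf("TOF ratio did not reach %.2f within %d s of sugammadex",
                cfg$tofr_target, cfg$reversal_cap_s),
        class = c("recurasim_protocol_failure", "error", "condition")
      ))
    }
    if (t >= end_s) break
    sim_advance(sim, dt)
  }
  c(ctl_log_collect(log),
    list(sgx_t0_s = t0, recovery_s = recovery_s,
         total_sgx_mg_kg = cfg$sgx_initial_mg_kg +
           n_supp * cfg$sgx_supplement_mg_kg,
         n_supplements = n_supp, end_time_s = sim_time(sim)))
}

#' Full protocol for one patient
#'
#' Induction, TOFC = 1 maintenance for the operation time, stepped
#' sugammadex reversal, and the post-reversal analysis window, run
#' closed-loop against a live simulation; then extracts the recovery
#' metrics.
#'
#' @param patient Patient covariates or a cohort row (which carries the
#'   individual parameter multipliers and operation time).
#' @param base_params Population parameter set, scaled per patient via
#'   [apply_covariates()] and the cohort multipliers.
#' @param cfg A [controller_config()].
#' @param op_time_s Operation (maintenance) duration, seconds; defaults
#'   to the cohort row's `op_time_h` or 2.5 h.
#' @param horizon_min Post-reversal analysis horizon, minutes.
#' @param rtol,atol Solver tolerances.
#' @return List with `trajectory`, `record` (device dosing record),
#'   `events`, `warnings`, `phases` (per-phase bookkeeping), and
#'   `metrics` (one-row data frame from [recovery_metrics()] plus
#'   protocol fields).
#' @export
run_protocol <- function(patient,
                         base_params = default_pkpd_parameters(),
                         cfg = controller_config(),
                         op_time_s = NULL,
                         horizon_min = 60,
                         rtol = 1e-8, atol = 1e-10) {
  pat <- as_patient(patient)
  if (is.null(op_time_s)) {
    op_time_s <- if (!is.null(pat$op_time_h)) {
      round(pat$op_time_h * 3600 / cfg$tof_interval_s) * cfg$tof_interval_s
    } else {
      9000
    }
  }
  params <- patient_parameters(pat, base_params)
  sim <- new_sim(params, rtol = rtol, atol = atol)
  ind <- run_induction(sim, pat, cfg)
  mnt <- run_maintenance(sim, pat, op_time_s, cfg,
                         start_rate_ug_min = ind$rate_ug_min)
  rev <- run_reversal(sim, pat, cfg, horizon_min = horizon_min)
  traj <- sim_trajectory(sim)
  record <- rbind(ind$record, mnt$record, rev$record)
  warnings <- rbind(ind$warnings, mnt$warnings, rev$warnings)
  met <- recovery_metrics(traj, rev$sgx_t0_s, horizon_min = horizon_min)
  met$target_ce <- target_ce(traj, mnt$end_time_s - 1800, mnt$end_time_s)
  met$recovery_obs_min <- rev$recovery_s / 60
  met$total_sgx_mg_kg <- rev$total_sgx_mg_kg
  met$n_supplements <- rev$n_supplements
  met$rb_dose_mg <- sum(attr(traj, "administered")[nrow(traj), "rb"]) / 1000
  met$op_time_h <- op_time_s / 3600
  list(
    trajectory = traj, record = record, events = sim_events(sim),
    warnings = warnings,
    phases = list(induction = ind[c("end_time_s", "rescue_given",
                                    "fallback_started_s", "blocked")],
                  maintenance = mnt[c("end_time_s", "rate_ug_min")],
                  reversal = rev[c("sgx_t0_s", "recovery_s",
                                   "total_sgx_mg_kg", "n_supplements")]),
    metrics = met
  )
}
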