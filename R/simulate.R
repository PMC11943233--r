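#' Dose events
#'
#' Timestamped bolus and infusion-rate events for either drug. An
#' `infusion_rate` event sets the active rate (ug/min) from its time
#' onward, until superseded; a `bolus` adds an amount (ug) to the central
#' compartment instantaneously.
#'
#' @param time_s Event times, seconds from simulation start (>= 0).
#' @param drug `"rb"` or `"sgx"` per event.
#' @param kind `"bolus"` or `"infusion_rate"` per event.
#' @param magnitude ug (bolus) or ug/min (rate), >= 0.
#' @return A `data.frame` of validated events sorted by time.
#' @export
dose_events <- function(time_s, drug, kind, magnitude) {
  ev <- data.frame(
    time_s = as.numeric(time_s),
    drug = as.character(drug),
    kind = as.character(kind),
    magnitude = as.numeric(magnitude),
    stringsAsFactors = FALSE
  )
  if (nrow(ev)) {
    stopifnot(
      all(ev$time_s >= 0), all(ev$magnitude >= 0),
      all(ev$drug %in% c("rb", "sgx")),
      all(ev$kind %in% c("bolus", "infusion_rate"))
    )
    ev <- ev[order(ev$time_s), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' Simulate the PK-PD system over a dosing schedule
#'
#' Integrates the coupled rocuronium/sugammadex/complex system with the
#' stiff-capable `lsoda` solver and the compiled model right-hand side.
#' Integration restarts at every dose event: boluses are instantaneous
#' central-amount increments and rate events switch the active infusion
#' rate; events are never interpolated across. The pharmacodynamic
#' channels (T1, TOF count, TOF ratio) are filled from the effect-site
#' concentration by [tof_from_ce()].
#'
#' Output rows report the state *just before* any event scheduled at that
#' time (so the time-zero row of a bolus schedule is drug-free), matching
#' the observe-then-dose convention of the closed-loop controller.
#'
#' @param events Events from [dose_events()].
#' @param params Parameter set.
#' @param duration_s Simulation length, seconds (> 0).
#' @param grid_dt Output grid step, seconds (default 12, the TOF cadence).
#' @param rtol,atol Solver tolerances.
#' @return A `pkpd_trajectory` data frame with columns `time_s`, `c_rb`,
#'   `c_sgx`, `c_comp` (central concentrations, ug/mL), `ce_rb`, `t1_pct`,
#'   `tofc`, `tofr`, and attributes `state`, `administered`, `params` used
#'   by [mass_balance()].
#' @export
simulate_pkpd <- function(events, params, duration_s, grid_dt = 12,
                          rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (nrow(events) && is.unsorted(events$time_s)) {
    stop("`events` must be sorted by time", call. = FALSE)
  }
  grid <- seq(0, duration_s, by = grid_dt)
  ev_times <- sort(unique(events$time_s[events$time_s < duration_s]))
  bounds <- sort(unique(c(0, ev_times, duration_s)))

  y <- empty_state()
  rates <- c(rb = 0, sgx = 0)
  given <- c(rb = 0, sgx = 0)
  states <- matrix(NA_real_, length(grid), length(y),
                   dimnames = list(NULL, state_names()))
  adm <- matrix(NA_real_, length(grid), 2,
                dimnames = list(NULL, c("rb", "sgx")))
  gi <- 1
  for (b in seq_len(length(bounds) - 1)) {
    t0 <- bounds[b]
    t1 <- bounds[b + 1]
    # grid points at the segment start carry the pre-event state
    while (gi <= length(grid) && grid[gi] <= t0) {
      states[gi, ] <- y
      adm[gi, ] <- given
      gi <- gi + 1
    }
    # apply events scheduled at t0, then integrate to t1
    if (nrow(events)) {
      here <- events[events$time_s == t0, , drop = FALSE]
      for (j in seq_len(nrow(here))) {
        e <- here[j, ]
        if (e$kind == "bolus") {
          slot <- if (e$drug == "rb") "a1_rb" else "a1_sgx"
          y[slot] <- y[slot] + e$magnitude
          given[e$drug] <- given[e$drug] + e$magnitude
        } else {
          rates[e$drug] <- e$magnitude
        }
      }
    }
    interior <- grid[grid > t0 & grid < t1]
    times <- c(t0, interior, t1)
    sol <- deSolve::lsoda(
      y = y, times = times, func = "rbsgx_derivs",
      parms = param_vector(params, rates[["rb"]], rates[["sgx"]]),
      dllname = "recurasim", initfunc = "rbsgx_init",
      rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed between t = ", t0, " and ", t1, " s",
           call. = FALSE)
    }
    for (j in seq_along(interior)) {
      states[gi, ] <- sol[1 + j, -1]
      adm[gi, ] <- given + rates * (interior[j] - t0) / 60
      gi <- gi + 1
    }
    y <- sol[nrow(sol), -1]
    names(y) <- state_names()
    given <- given + rates * (t1 - t0) / 60
  }
  while (gi <= length(grid)) {
    states[gi, ] <- y
    adm[gi, ] <- given
    gi <- gi + 1
  }
  build_trajectory(grid, states, adm, params)
}

# Assemble the exported trajectory data frame from raw states.
build_trajectory <- function(time_s, states, administered, params) {
  pd <- tof_from_ce(pmax(states[, "ce_rb"], 0), params)
  traj <- data.frame(
    time_s = time_s,
    c_rb = states[, "a1_rb"] / (params$v1_rb * 1000),
    c_sgx = states[, "a1_sgx"] / (params$v1_sgx * 1000),
    c_comp = states[, "ac1"] * (params$mw_rb + params$mw_sgx) /
      (params$v1_cx * 1000),
    ce_rb = states[, "ce_rb"],
    t1_pct = pd$t1_pct,
    tofc = pd$tofc,
    tofr = pd$tofr
  )
  attr(traj, "state") <- states
  attr(traj, "administered") <- administered
  attr(traj, "params") <- params
  class(traj) <- c("pkpd_trajectory", "data.frame")
  traj
}

#' Export a trajectory to CSV
#'
#' Writes the standard eight-column trajectory table
#' (`time_s, c_rb, c_sgx, c_comp, ce_rb, t1_pct, tofc, tofr`).
#'
#' @param traj Trajectory data frame.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c(
    "time_s", "c_rb", "c_sgx", "c_comp", "ce_rb", "t1_pct", "tofc", "tofr"
  )], path, row.names = FALSE)
  invisible(path)
}
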