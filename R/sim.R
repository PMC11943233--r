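#' Live simulation handle
#'
#' A stateful handle for closed-loop use: the controller observes the
#' current TOF response, issues doses, and advances the integration one
#' TOF interval at a time. The handle records the full state trajectory
#' and every dose event, so the finished run can be exported as a
#' trajectory ([sim_trajectory()]) and a device-style dosing record.
#'
#' @param params Parameter set ([default_pkpd_parameters()]).
#' @param rtol,atol Solver tolerances.
#' @return An environment of class `pkpd_sim`.
#' @export
new_sim <- function(params, rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  sim <- new.env(parent = emptyenv())
  sim$params <- params
  sim$rtol <- rtol
  sim$atol <- atol
  sim$t <- 0
  sim$y <- empty_state()
  sim$rates <- c(rb = 0, sgx = 0)
  sim$given <- c(rb = 0, sgx = 0)
  n0 <- 4096
  sim$n <- 0L
  sim$times <- numeric(n0)
  sim$states <- matrix(NA_real_, n0, length(sim$y),
                       dimnames = list(NULL, state_names()))
  sim$adm <- matrix(NA_real_, n0, 2, dimnames = list(NULL, c("rb", "sgx")))
  sim$events <- list()
  class(sim) <- "pkpd_sim"
  sim
}

#' @rdname new_sim
#' @param sim A simulation handle.
#' @export
sim_time <- function(sim) UseMethod("sim_time")

#' @export
sim_time.pkpd_sim <- function(sim) sim$t

#' Observe the current TOF response
#'
#' Returns the instantaneous observation the controller sees: time,
#' concentrations, T1, TOF count and TOF ratio, and records the state on
#' the trajectory log (one row per observation tick).
#'
#' @param sim A simulation handle.
#' @return One-row data frame.
#' @export
sim_observe <- function(sim) UseMethod("sim_observe")

#' @export
sim_observe.pkpd_sim <- function(sim) {
  p <- sim$params
  pd <- tof_from_ce(max(sim$y[["ce_rb"]], 0), p)
  sim$n <- sim$n + 1L
  if (sim$n > length(sim$times)) {
    grow <- length(sim$times)
    sim$times <- c(sim$times, numeric(grow))
    sim$states <- rbind(sim$states, matrix(NA_real_, grow, ncol(sim$states)))
    sim$adm <- rbind(sim$adm, matrix(NA_real_, grow, 2))
  }
  sim$times[sim$n] <- sim$t
  sim$states[sim$n, ] <- sim$y
  sim$adm[sim$n, ] <- sim$given
  data.frame(
    time_s = sim$t,
    ce_rb = sim$y[["ce_rb"]],
    c_rb = sim$y[["a1_rb"]] / (p$v1_rb * 1000),
    t1_pct = pd$t1_pct, tofc = pd$tofc, tofr = pd$tofr
  )
}

#' Issue a bolus dose on a live simulation
#'
#' @param sim A simulation handle.
#' @param drug `"rb"` or `"sgx"`.
#' @param amount_ug Bolus amount, ug (>= 0).
#' @export
sim_bolus <- function(sim, drug, amount_ug) UseMethod("sim_bolus")

#' @export
sim_bolus.pkpd_sim <- function(sim, drug, amount_ug) {
  stopifnot(drug %in% c("rb", "sgx"), amount_ug >= 0)
  slot <- if (drug == "rb") "a1_rb" else "a1_sgx"
  sim$y[slot] <- sim$y[slot] + amount_ug
  sim$given[drug] <- sim$given[drug] + amount_ug
  sim$events[[length(sim$events) + 1L]] <-
    list(time_s = sim$t, drug = drug, kind = "bolus", magnitude = amount_ug)
  invisible(sim)
}

#' Set an infusion rate on a live simulation
#'
#' @param sim A simulation handle.
#' @param drug `"rb"` or `"sgx"`.
#' @param rate_ug_min New rate, ug/min (>= 0); persists until superseded.
#' @export
sim_set_rate <- function(sim, drug, rate_ug_min) UseMethod("sim_set_rate")

#' @export
sim_set_rate.pkpd_sim <- function(sim, drug, rate_ug_min) {
  stopifnot(drug %in% c("rb", "sgx"), rate_ug_min >= 0)
  sim$rates[drug] <- rate_ug_min
  sim$events[[length(sim$events) + 1L]] <-
    list(time_s = sim$t, drug = drug, kind = "infusion_rate",
         magnitude = rate_ug_min)
  invisible(sim)
}

#' Advance a live simulation
#'
#' Integrates the system forward by `dt_s` seconds under the currently
#' active infusion rates.
#'
#' @param sim A simulation handle.
#' @param dt_s Step, seconds (> 0).
#' @export
sim_advance <- function(sim, dt_s) UseMethod("sim_advance")

#' @export
sim_advance.pkpd_sim <- function(sim, dt_s) {
  stopifnot(dt_s > 0)
  sol <- deSolve::lsoda(
    y = sim$y, times = c(sim$t, sim$t + dt_s), func = "rbsgx_derivs",
    parms = param_vector(sim$params, sim$rates[["rb"]], sim$rates[["sgx"]]),
    dllname = "recurasim", initfunc = "rbsgx_init",
    rtol = sim$rtol, atol = sim$atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed at t = ", sim$t, " s", call. = FALSE)
  }
  sim$y <- sol[2, -1]
  names(sim$y) <- state_names()
  sim$given <- sim$given + sim$rates * dt_s / 60
  sim$t <- sim$t + dt_s
  invisible(sim)
}

#' Trajectory recorded by a live simulation
#'
#' One row per observation tick, same layout and attributes as
#' [simulate_pkpd()] output.
#'
#' @param sim A simulation handle.
#' @export
sim_trajectory <- function(sim) {
  n <- sim$n
  build_trajectory(sim$times[seq_len(n)],
                   sim$states[seq_len(n), , drop = FALSE],
                   sim$adm[seq_len(n), , drop = FALSE], sim$params)
}

#' Dose events emitted on a live simulation
#'
#' @param sim A simulation handle.
#' @export
sim_events <- function(sim) {
  if (!length(sim$events)) {
    return(dose_events(numeric(), character(), character(), numeric()))
  }
  ev <- do.call(rbind, lapply(sim$events, as.data.frame))
  dose_events(ev$time_s, ev$drug, ev$kind, ev$magnitude)
}
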