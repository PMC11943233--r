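#' System state vector
#'
#' Amounts of free rocuronium and sugammadex (ug, central/peripheral),
#' complex (umol, central/peripheral), the rocuronium effect-site
#' concentration (ug/mL), and cumulative eliminated mass per species (ug,
#' including drug carried out of the body inside the complex).
#'
#' @return Named numeric vector of length 9, all zero (drug-free state).
#' @export
empty_state <- function() {
  c(a1_rb = 0, a2_rb = 0, a1_sgx = 0, a2_sgx = 0,
    ac1 = 0, ac2 = 0, ce_rb = 0, elim_rb = 0, elim_sgx = 0)
}

state_names <- function() names(empty_state())

#' Model right-hand side (reference implementation)
#'
#' Time derivative of the system state, in R. The simulation engine uses
#' the identical compiled version (`src/rbsgx.c`); this function is the
#' readable reference used in tests and for derivative-level checks.
#'
#' Each species follows linear two-compartment disposition. Free Rb and
#' free SGX associate 1:1 in the central compartment at a molar rate
#' `kon * [Rb] * [SGX] * V1_rb` (concentrations in uM), the complex
#' dissociates at `koff` and is itself distributed and eliminated with
#' sugammadex-like (renal) parameters. Mass and molar units are bridged by
#' the molecular weights.
#'
#' @param state Named state vector as in [empty_state()]; time unit
#'   seconds.
#' @param params Parameter set ([default_pkpd_parameters()]).
#' @param rates Named vector `c(rb = , sgx = )`, active infusion rates in
#'   ug/min.
#' @return Named derivative vector, per second.
#' @export
ode_rhs <- function(state, params, rates = c(rb = 0, sgx = 0)) {
  if (any(state < -1e-8)) {
    stop("negative state entries: integration guard", call. = FALSE)
  }
  s <- pmax(state, 0)
  p <- params
  crb_uM <- s[["a1_rb"]] / (p$mw_rb * p$v1_rb)
  csx_uM <- s[["a1_sgx"]] / (p$mw_sgx * p$v1_sgx)
  jbind <- p$kon * crb_uM * csx_uM * p$v1_rb
  jdiss <- p$koff * s[["ac1"]]

  dist_r <- p$q_rb * (s[["a1_rb"]] / p$v1_rb - s[["a2_rb"]] / p$v2_rb)
  dist_s <- p$q_sgx * (s[["a1_sgx"]] / p$v1_sgx - s[["a2_sgx"]] / p$v2_sgx)
  dist_c <- p$q_cx * (s[["ac1"]] / p$v1_cx - s[["ac2"]] / p$v2_cx)
  el_r <- p$cl_rb * s[["a1_rb"]] / p$v1_rb
  el_s <- p$cl_sgx * s[["a1_sgx"]] / p$v1_sgx
  el_c <- p$cl_cx * s[["ac1"]] / p$v1_cx

  d_min <- c(
    a1_rb = rates[["rb"]] - el_r - dist_r - p$mw_rb * jbind + p$mw_rb * jdiss,
    a2_rb = dist_r,
    a1_sgx = rates[["sgx"]] - el_s - dist_s - p$mw_sgx * jbind + p$mw_sgx * jdiss,
    a2_sgx = dist_s,
    ac1 = jbind - jdiss - el_c - dist_c,
    ac2 = dist_c,
    ce_rb = p$ke0 * (s[["a1_rb"]] / (p$v1_rb * 1000) - s[["ce_rb"]]),
    elim_rb = el_r + p$mw_rb * el_c,
    elim_sgx = el_s + p$mw_sgx * el_c
  )
  d_min / 60
}

#' Per-species mass balance of a trajectory
#'
#' For every output time, compares the administered dose against the sum
#' of free amounts, complex-bound equivalents and cumulative eliminated
#' mass. The relative error should be at the integrator tolerance
#' (default solver settings: well below 1e-6 of the administered dose).
#'
#' @param traj A trajectory from [simulate_pkpd()] or a controller run.
#' @return Data frame with per-tick relative errors `err_rb`, `err_sgx`
#'   (zero doses give zero error by convention).
#' @export
mass_balance <- function(traj) {
  st <- attr(traj, "state")
  adm <- attr(traj, "administered")
  if (is.null(st) || is.null(adm)) {
    stop("trajectory carries no state/administered attributes", call. = FALSE)
  }
  p <- attr(traj, "params")
  tot_rb <- st[, "a1_rb"] + st[, "a2_rb"] +
    p$mw_rb * (st[, "ac1"] + st[, "ac2"]) + st[, "elim_rb"]
  tot_sgx <- st[, "a1_sgx"] + st[, "a2_sgx"] +
    p$mw_sgx * (st[, "ac1"] + st[, "ac2"]) + st[, "elim_sgx"]
  rel <- function(total, given) {
    ifelse(given > 0, abs(total - given) / given, abs(total - given))
  }
  data.frame(
    time_s = traj$time_s,
    err_rb = rel(tot_rb, adm[, "rb"]),
    err_sgx = rel(tot_sgx, adm[, "sgx"])
  )
}
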