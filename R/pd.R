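#' Train-of-four response from effect-site concentration
#'
#' Maps the rocuronium effect-site concentration to the evoked twitch
#' pattern. The first twitch follows a sigmoid Emax (Hill) model,
#' `T1 = 100 * (1 - Ce^g / (Ce^g + EC50^g))` (% of control); the later
#' twitches T2..T4 use the same model with progressively lower EC50
#' (fade), so T4 disappears first as the block deepens. The TOF count is
#' the number of twitches at or above the detection threshold (default 5%
#' of control), and the TOF ratio is T4/T1, defined only when all four
#' twitches are present.
#'
#' @param ce Effect-site concentration(s), ug/mL, >= 0.
#' @param params Parameter set; uses `ec50_t1`, `hill_gamma`,
#'   `fade_t2..t4`, `detect_threshold`.
#' @return Data frame with columns `t1_pct`, `tofc`, `tofr` (`tofr` is
#'   `NA` when `tofc < 4`).
#' @export
#' @examples
#' tof_from_ce(c(0, 0.8, 5), default_pkpd_parameters())
tof_from_ce <- function(ce, params) {
  if (any(ce < 0)) stop("`ce` must be non-negative", call. = FALSE)
  ec50 <- params$ec50_t1 *
    c(1, params$fade_t2, params$fade_t3, params$fade_t4)
  g <- params$hill_gamma
  tw <- sapply(ec50, function(e) {
    h <- ce^g / (ce^g + e^g)
    h[ce == 0] <- 0
    100 * (1 - h)
  })
  tw <- matrix(tw, ncol = 4)
  detected <- tw >= params$detect_threshold
  tofc <- rowSums(detected)
  tofr <- ifelse(tofc == 4, tw[, 4] / tw[, 1], NA_real_)
  data.frame(t1_pct = tw[, 1], tofc = as.integer(tofc), tofr = tofr)
}

#' Effect-site concentration from a plasma profile
#'
#' First-order effect-compartment link, `dCe/dt = ke0 (C - Ce)` with
#' `Ce(0) = 0`. The input profile is treated as piecewise linear between
#' samples and the linear ODE is advanced with its exact (exponential
#' integrator) update, so a constant input reproduces
#' `Ce(t) = C (1 - exp(-ke0 t))` to machine precision.
#'
#' @param time_s Sample times, seconds, strictly increasing from 0.
#' @param conc Plasma concentration at `time_s` (ug/mL).
#' @param ke0 Equilibration rate constant, 1/min, > 0.
#' @return Numeric vector `Ce` on the same grid.
#' @export
effect_site_concentration <- function(time_s, conc, ke0) {
  if (ke0 <= 0) stop("`ke0` must be positive", call. = FALSE)
  if (length(time_s) != length(conc)) {
    stop("`time_s` and `conc` must have equal length", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  k <- ke0 / 60 # per second
  n <- length(conc)
  ce <- numeric(n)
  for (i in seq_len(n - 1)) {
    dt <- time_s[i + 1] - time_s[i]
    c0 <- conc[i]
    slope <- (conc[i + 1] - c0) / dt
    e <- exp(-k * dt)
    ce[i + 1] <- ce[i] * e + c0 * (1 - e) +
      slope * (dt - (1 - e) / k)
  }
  ce
}
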