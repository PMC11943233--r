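# Analytic solution of a linear two-compartment model after a single
# central bolus: C1(t) = A exp(-l1 t) + B exp(-l2 t). Independent of the
# ODE engine (eigenvalue closed form).
two_cpt_bolus_conc <- function(dose_ug, v1, v2, cl, q, t_min) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  root <- sqrt(s^2 - 4 * k10 * k21)
  l1 <- (s + root) / 2
  l2 <- (s - root) / 2
  c0 <- dose_ug / (v1 * 1000) # ug/mL
  a <- c0 * (l1 - k21) / (l1 - l2)
  b <- c0 * (k21 - l2) / (l1 - l2)
  a * exp(-l1 * t_min) + b * exp(-l2 * t_min)
}

# Small-step forward-Euler integration of the full model using the R
# right-hand side; independent check of solver output over short spans.
euler_integrate <- function(state, params, rates, dt_s, n_steps) {
  for (i in seq_len(n_steps)) {
    state <- state + dt_s * ode_rhs(state, params, rates)
    state <- pmax(state, 0)
  }
  state
}

# Reference patient used across tests (identity point of the covariate
# model, unit multipliers).
ref_patient <- function(params = default_pkpd_parameters()) {
  reference_covariates(params)
}
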