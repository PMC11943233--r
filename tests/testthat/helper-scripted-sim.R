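# A scripted stand-in for the live simulation handle: replays a fixed
# TOF observation stream so controller *rules* (dose ladder, timing) can
# be tested in isolation from the PK-PD engine.
new_scripted_sim <- function(tofc, tofr, dt_s = 12) {
  sim <- new.env(parent = emptyenv())
  sim$tofc <- tofc
  sim$tofr <- tofr
  sim$dt <- dt_s
  sim$i <- 1L
  sim$t <- 0
  sim$events <- list()
  class(sim) <- "scripted_sim"
  sim
}

sim_time.scripted_sim <- function(sim) sim$t

sim_observe.scripted_sim <- function(sim) {
  i <- min(sim$i, length(sim$tofc))
  data.frame(time_s = sim$t, ce_rb = NA_real_, c_rb = NA_real_,
             t1_pct = NA_real_, tofc = sim$tofc[i], tofr = sim$tofr[i])
}

sim_advance.scripted_sim <- function(sim, dt_s) {
  sim$t <- sim$t + dt_s
  sim$i <- sim$i + 1L
  invisible(sim)
}

sim_bolus.scripted_sim <- function(sim, drug, amount_ug) {
  sim$events[[length(sim$events) + 1L]] <-
    list(time_s = sim$t, drug = drug, kind = "bolus", magnitude = amount_ug)
  invisible(sim)
}

sim_set_rate.scripted_sim <- function(sim, drug, rate_ug_min) {
  sim$events[[length(sim$events) + 1L]] <-
    list(time_s = sim$t, drug = drug, kind = "infusion_rate",
         magnitude = rate_ug_min)
  invisible(sim)
}

local({
  ns <- asNamespace("recurasim")
  registerS3method("sim_time", "scripted_sim", sim_time.scripted_sim, ns)
  registerS3method("sim_observe", "scripted_sim", sim_observe.scripted_sim, ns)
  registerS3method("sim_advance", "scripted_sim", sim_advance.scripted_sim, ns)
  registerS3method("sim_bolus", "scripted_sim", sim_bolus.scripted_sim, ns)
  registerS3method("sim_set_rate", "scripted_sim", sim_set_rate.scripted_sim, ns)
})

scripted_events <- function(sim) {
  do.call(rbind, lapply(sim$events, as.data.frame))
}
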