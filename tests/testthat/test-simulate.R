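test_that("single bolus with binding disabled matches the bi-exponential closed form", {
  p <- default_pkpd_parameters(kon = 1e-12)
  dose <- 30000
  ev <- dose_events(0, "rb", "bolus", dose)
  traj <- simulate_pkpd(ev, p, duration_s = 7200, grid_dt = 12)
  t_min <- traj$time_s[-1] / 60
  expected <- two_cpt_bolus_conc(dose, p$v1_rb, p$v2_rb, p$cl_rb, p$q_rb,
                                 t_min)
  rel <- abs(traj$c_rb[-1] - expected) / expected
  expect_lt(max(rel), 1e-4)
})

test_that("linear PK: doubling all doses doubles all concentrations", {
  p <- default_pkpd_parameters(kon = 1e-12)
  ev1 <- dose_events(c(0, 0, 600), c("rb", "sgx", "rb"),
                     c("bolus", "bolus", "infusion_rate"),
                     c(20000, 80000, 300))
  ev2 <- ev1
  ev2$magnitude <- 2 * ev2$magnitude
  t1 <- simulate_pkpd(ev1, p, 3600, grid_dt = 60)
  t2 <- simulate_pkpd(ev2, p, 3600, grid_dt = 60)
  for (col in c("c_rb", "c_sgx", "ce_rb")) {
    expect_equal(t2[[col]], 2 * t1[[col]], tolerance = 1e-7)
  }
})

test_that("a sugammadex bolus on a rocuronium steady state captures free drug", {
  p <- default_pkpd_parameters()
  # run rocuronium to near steady state, then bolus sugammadex
  ev <- dose_events(c(0, 7200), c("rb", "sgx"),
                    c("infusion_rate", "bolus"), c(400, 112600))
  traj <- simulate_pkpd(ev, p, duration_s = 7260, grid_dt = 12)
  i0 <- which(traj$time_s == 7200) # pre-bolus row
  expect_lt(traj$c_rb[i0 + 1], traj$c_rb[i0])
  expect_gt(traj$c_comp[i0 + 1], traj$c_comp[i0])
  # against a small-step Euler oracle over the first grid step
  st <- attr(traj, "state")[i0, ]
  st["a1_sgx"] <- st["a1_sgx"] + 112600
  euler <- euler_integrate(st, p, c(rb = 0, sgx = 0), dt_s = 5e-4,
                           n_steps = 24000) # 12 s, binding is stiff
  expect_lt(euler[["a1_rb"]], attr(traj, "state")[i0, "a1_rb"])
  expect_equal(unname(euler[1:6]),
               unname(attr(traj, "state")[i0 + 1, 1:6]), tolerance = 5e-3)
})

test_that("mass balance holds at every output tick of a dosed run", {
  p <- default_pkpd_parameters()
  ev <- dose_events(c(0, 0, 1800, 3600), c("rb", "rb", "sgx", "sgx"),
                    c("bolus", "infusion_rate", "infusion_rate", "bolus"),
                    c(30000, 350, 2000, 112600))
  traj <- simulate_pkpd(ev, p, duration_s = 5400, grid_dt = 12)
  mb <- mass_balance(traj)
  expect_lt(max(mb$err_rb), 1e-6)
  expect_lt(max(mb$err_sgx), 1e-6)
  st <- attr(traj, "state")
  expect_true(all(st >= -1e-9))
  expect_true(all(traj$c_rb >= 0 & traj$c_sgx >= 0 & traj$c_comp >= 0))
})

test_that("events must be sorted and duration positive", {
  p <- default_pkpd_parameters()
  ev <- dose_events(c(60, 0), c("rb", "rb"), c("bolus", "bolus"),
                    c(1, 1)) # constructor sorts
  expect_silent(simulate_pkpd(ev, p, 120, grid_dt = 60))
  bad <- ev[c(2, 1), ]
  expect_error(simulate_pkpd(bad, p, 120), "sorted")
  expect_error(simulate_pkpd(ev, p, 0), "positive")
})

test_that("replaying a controller dosing record reproduces the closed-loop trajectory", {
  res <- cached_reference_run()
  rec <- res$record
  path <- withr::local_tempfile(fileext = ".csv")
  write_dosing_record(rec, path)
  ev <- read_dosing_record(path)
  p <- patient_parameters(ref_patient())
  dur <- max(rec$time_s) + 12
  replay <- simulate_pkpd(ev, p, duration_s = dur, grid_dt = 12)
  both <- merge(as.data.frame(res$trajectory), as.data.frame(replay),
                by = "time_s", suffixes = c("_live", "_replay"))
  # induction boluses are smeared over one 12-s interval in the record,
  # so compare after the distribution phase
  late <- both[both$time_s > 600, ]
  rel <- abs(late$ce_rb_live - late$ce_rb_replay) /
    pmax(late$ce_rb_live, 1e-4)
  expect_lt(max(rel), 0.02)
})

test_that("post-reversal free drug shows one nadir and at most one rebound", {
  res <- cached_reference_run()
  tr <- res$trajectory
  t0 <- res$phases$reversal$sgx_t0_s
  ce <- tr$ce_rb[tr$time_s >= t0 + 60] # past the bolus transient
  d <- diff(ce)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  expect_lte(sign_changes, 2)
  expect_equal(res$metrics$rebound, TRUE)
  expect_false(res$metrics$recur)
})
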