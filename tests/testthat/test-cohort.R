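test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(10, seed = 99)
  b <- generate_cohort(10, seed = 99)
  expect_identical(a, b)
  c2 <- generate_cohort(10, seed = 100)
  expect_false(identical(a, c2))
})

test_that("hard exclusions hold for every sampled patient", {
  coh <- generate_cohort(2000, seed = 3)
  expect_true(all(coh$bmi >= 18 & coh$bmi <= 26))
  expect_true(all(coh$age_y >= 20))
  expect_true(all(coh$op_time_h >= 0.5))
  expect_true(all(coh$scr_mg_dl > 0))
  expect_true(all(coh$weight_kg > 0))
})

test_that("creatinine back-solve round-trips to the sampled eCCr", {
  coh <- generate_cohort(200, seed = 11)
  eccr <- mapply(cockcroft_gault, coh$age_y, coh$weight_kg,
                 coh$scr_mg_dl, coh$sex)
  expect_equal(eccr, coh$eccr_ml_min, tolerance = 1e-9)
})

test_that("cohort statistics recover the configured distribution", {
  # closed-form truncated-normal moments are the oracle
  tn_moments <- function(spec) {
    mu <- spec[1]; s <- spec[2]
    a <- (spec[3] - mu) / s; b <- (spec[4] - mu) / s
    z <- pnorm(b) - pnorm(a)
    m <- mu + s * (dnorm(a) - dnorm(b)) / z
    v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                  ((dnorm(a) - dnorm(b)) / z)^2)
    c(mean = m, sd = sqrt(v))
  }
  cfg <- cohort_config()
  n <- 5000
  coh <- generate_cohort(n, seed = 5)
  vars <- list(age_y = cfg$age, height_cm = cfg$height, bmi = cfg$bmi,
               eccr_ml_min = cfg$eccr, op_time_h = cfg$op_time)
  for (v in names(vars)) {
    mo <- tn_moments(vars[[v]])
    x <- coh[[v]]
    expect_lt(abs(mean(x) - mo["mean"]), 3 * mo["sd"] / sqrt(n))
    expect_lt(abs(sd(x) - mo["sd"]), 3 * mo["sd"] / sqrt(2 * n))
  }
  expect_lt(abs(mean(coh$sex == "female") - cfg$female_fraction),
            3 * sqrt(cfg$female_fraction * (1 - cfg$female_fraction) / n))
  # log-normal multipliers: unit mean, configured CV
  expect_equal(mean(coh$m_ec50), 1, tolerance = 0.05)
  expect_equal(sd(coh$m_ec50) / mean(coh$m_ec50), cfg$cv_ec50,
               tolerance = 0.1)
})

test_that("Table-level cohort of 74 and the 1000-patient checks", {
  coh <- generate_cohort(74, seed = 2)
  expect_equal(nrow(coh), 74L)
  big <- generate_cohort(1000, seed = 8)
  expect_lt(abs(mean(big$age_y) - 62.2), 1.5)
  expect_lt(abs(mean(big$eccr_ml_min) - 75.9), 2.5)
  expect_lt(abs(mean(big$sex == "female") - 49 / 74), 0.05)
})

test_that("unsatisfiable truncation bounds are a configuration error", {
  cfg <- cohort_config(age = c(62.2, 1, 200, 210))
  expect_error(generate_cohort(5, 1, cfg), "probability mass")
  expect_error(cohort_config(bmi = c(22, -1, 18, 26)), "sd > 0")
  expect_error(generate_cohort(0, 1), ">= 1")
})

test_that("individual multipliers reach the scaled parameter set", {
  coh <- generate_cohort(3, seed = 21)
  pat <- coh[2, ]
  p <- patient_parameters(pat)
  cov <- patient_covariates(pat$sex, pat$age_y, pat$height_cm,
                            pat$weight_kg, pat$scr_mg_dl)
  p0 <- apply_covariates(default_pkpd_parameters(), cov)
  expect_equal(p$cl_rb, p0$cl_rb * pat$m_cl, tolerance = 1e-12)
  expect_equal(p$v1_sgx, p0$v1_sgx * pat$m_v1, tolerance = 1e-12)
  expect_equal(p$ec50_t1, p0$ec50_t1 * pat$m_ec50, tolerance = 1e-12)
})

test_that("cohort CSV round-trips", {
  coh <- generate_cohort(6, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh, tolerance = 1e-12)
})
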