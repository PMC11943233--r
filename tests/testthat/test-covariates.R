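test_that("ideal body weight follows the Devine convention", {
  # 177.8 cm = 70 in = 10 in over 5 ft: 50 + 2.3 * 10
  expect_equal(ideal_body_weight(177.8, "male"), 73.0)
  expect_equal(ideal_body_weight(152.4, "male"), 50.0)
  expect_equal(ideal_body_weight(152.4, "female"), 45.5)
  expect_error(ideal_body_weight(0, "male"), "positive")
})

test_that("Cockcroft-Gault evaluates the printed formula", {
  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100.0)
  expect_equal(cockcroft_gault(40, 72, 1.0, "female"), 85.0)
  expect_equal(cockcroft_gault(139.999999, 72, 1.0, "male"), 0,
               tolerance = 1e-5)
  expect_error(cockcroft_gault(40, 72, 0, "male"), "positive")
  expect_error(cockcroft_gault(40, -1, 1, "male"), "positive")
})

test_that("Cockcroft-Gault inverse round-trips through the forward formula", {
  for (sex in c("male", "female")) {
    scr <- cockcroft_gault_inverse(63, 58, 76.4, sex)
    expect_equal(cockcroft_gault(63, 58, scr, sex), 76.4, tolerance = 1e-12)
  }
})

test_that("covariate scaling is the identity at the reference patient", {
  base <- default_pkpd_parameters()
  scaled <- apply_covariates(base, reference_covariates(base))
  expect_equal(unclass(scaled), unclass(base), tolerance = 1e-12)
})

test_that("sugammadex clearance scales monotonically with renal function", {
  base <- default_pkpd_parameters()
  mk <- function(eccr) {
    scr <- cockcroft_gault_inverse(base$ref_age, base$ref_weight, eccr,
                                   "female")
    patient_covariates("female", base$ref_age, 159, base$ref_weight, scr)
  }
  lo <- apply_covariates(base, mk(60))
  hi <- apply_covariates(base, mk(120))
  expect_gt(hi$cl_sgx, lo$cl_sgx)
  expect_gt(hi$cl_cx, lo$cl_cx)
  # volumes are not renal-function dependent
  expect_equal(hi$v1_sgx, lo$v1_sgx)
})

test_that("the Asian flag touches only the flagged potency parameter", {
  base <- default_pkpd_parameters()
  cov_a <- reference_covariates(base)
  cov_n <- cov_a
  cov_n$asian <- FALSE
  a <- apply_covariates(base, cov_a)
  n <- apply_covariates(base, cov_n)
  expect_false(isTRUE(all.equal(a$ec50_t1, n$ec50_t1)))
  same <- setdiff(names(a), "ec50_t1")
  expect_equal(unclass(a)[same], unclass(n)[same], tolerance = 1e-12)
})

test_that("parameter validation rejects broken sets", {
  expect_error(default_pkpd_parameters(cl_rb = -1), "positive")
  expect_error(default_pkpd_parameters(hill_gamma = 0.5), ">= 1")
  expect_error(default_pkpd_parameters(fade_t2 = 0.5, fade_t3 = 0.6),
               "fade")
  expect_error(default_pkpd_parameters(nonsense = 1), "unknown")
})

test_that("parameter files round-trip through YAML", {
  p <- default_pkpd_parameters(cl_sgx = 0.123, ec50_t1 = 0.91)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- read_parameters(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_error(read_parameters(withr::local_tempfile(fileext = ".yaml",
                                                     lines = "a: 1")),
               "not a recurasim parameter file")
})
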