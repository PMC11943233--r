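#' Synthetic cohort configuration
#'
#' Distributional targets for the virtual patients, defaulting to the
#' study cohort: age 62.2 +/- 14.0 y, height 159.0 +/- 7.8 cm, BMI
#' 22.3 +/- 2.2 kg/m2 hard-truncated to the 18-26 inclusion window, eCCr
#' 75.9 +/- 20.6 mL/min, 49/74 female, operation time 2.5 +/- 1.0 h
#' (lower bound 0.5 h). Weight is derived from BMI and height; serum
#' creatinine is back-solved from the sampled eCCr target through the
#' Cockcroft-Gault inverse, so the printed eCCr distribution is
#' reproduced exactly. Between-subject variability is log-normal on
#' clearance, central volume and potency (EC50); the default coefficients
#' of variation (30/30/40%) are chosen so cohort-level outputs spread
#' over the printed clinical ranges.
#'
#' Each variable is a vector `c(mean, sd, lo, hi)`; sampling is
#' truncated-normal by rejection.
#'
#' @param age,height,bmi,eccr,op_time `c(mean, sd, lo, hi)` per variable.
#' @param female_fraction Probability a sampled patient is female.
#' @param cv_cl,cv_v1,cv_ec50 Log-normal between-subject CVs.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(age = c(62.2, 14.0, 20, 95),
                          height = c(159.0, 7.8, 135, 185),
                          bmi = c(22.3, 2.2, 18, 26),
                          eccr = c(75.9, 20.6, 25, 140),
                          op_time = c(2.5, 1.0, 0.5, 6),
                          female_fraction = 49 / 74,
                          cv_cl = 0.30, cv_v1 = 0.30, cv_ec50 = 0.40) {
  cfg <- as.list(environment())
  for (nm in c("age", "height", "bmi", "eccr", "op_time")) {
    v <- cfg[[nm]]
    if (length(v) != 4 || v[2] <= 0 || v[3] >= v[4]) {
      stop("`", nm, "` must be c(mean, sd, lo, hi) with sd > 0, lo < hi",
           call. = FALSE)
    }
  }
  stopifnot(female_fraction >= 0, female_fraction <= 1,
            cv_cl > 0, cv_v1 > 0, cv_ec50 > 0)
  class(cfg) <- "cohort_config"
  cfg
}

# Truncated-normal sampling by rejection (documented design choice:
# exact bounds, no density re-weighting subtleties).
rtrunc_norm <- function(n, spec) {
  mean <- spec[1]; sd <- spec[2]; lo <- spec[3]; hi <- spec[4]
  if (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd) < 1e-6) {
    stop("truncation bounds exclude essentially all probability mass",
         call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

lognorm_mult <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Sample one virtual patient
#'
#' Draws covariates and individual parameter multipliers using the
#' current RNG state. The log-normal multipliers have unit mean.
#'
#' @param config A [cohort_config()].
#' @return One-row data frame (see [generate_cohort()] for columns).
#' @export
sample_patient <- function(config = cohort_config()) {
  generate_cohort_rows(1, config)
}

generate_cohort_rows <- function(n, config) {
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- rtrunc_norm(n, config$age)
  height <- rtrunc_norm(n, config$height)
  bmi <- rtrunc_norm(n, config$bmi)
  weight <- bmi * (height / 100)^2
  eccr <- rtrunc_norm(n, config$eccr)
  scr <- mapply(cockcroft_gault_inverse, age, weight, eccr, sex)
  op <- rtrunc_norm(n, config$op_time)
  data.frame(
    id = seq_len(n),
    sex = sex, age_y = age, height_cm = height, weight_kg = weight,
    bmi = bmi, scr_mg_dl = scr, eccr_ml_min = eccr, op_time_h = op,
    m_cl = lognorm_mult(n, config$cv_cl),
    m_v1 = lognorm_mult(n, config$cv_v1),
    m_ec50 = lognorm_mult(n, config$cv_ec50),
    stringsAsFactors = FALSE
  )
}

#' Generate a virtual cohort
#'
#' @param n Number of patients (>= 1).
#' @param seed RNG seed (the whole cohort is reproducible from it).
#' @param config A [cohort_config()].
#' @return Data frame, one row per patient: demographics, back-solved
#'   serum creatinine, operation time, and the individual log-normal
#'   parameter multipliers `m_cl`, `m_v1`, `m_ec50`.
#' @export
generate_cohort <- function(n, seed, config = cohort_config()) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(seed)
  generate_cohort_rows(n, config)
}

#' @rdname generate_cohort
#' @param cohort A cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname generate_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Normalize a patient argument: accepts patient_covariates or a one-row
# cohort data frame; returns a plain list with covariates, multipliers
# and (optionally) the operation time.
as_patient <- function(x) {
  if (inherits(x, "patient_covariates")) {
    out <- unclass(x)
    out$m_cl <- out$m_v1 <- out$m_ec50 <- 1
    return(out)
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    out <- as.list(x)
    if (is.null(out$asian)) out$asian <- TRUE
    if (is.null(out$m_cl)) out$m_cl <- 1
    if (is.null(out$m_v1)) out$m_v1 <- 1
    if (is.null(out$m_ec50)) out$m_ec50 <- 1
    return(out)
  }
  if (is.list(x)) return(x)
  stop("cannot interpret `patient`", call. = FALSE)
}

#' Individual parameter set for one patient
#'
#' Covariate scaling ([apply_covariates()]) followed by the patient's
#' log-normal multipliers: `m_cl` on all clearances, `m_v1` on the
#' central volumes, `m_ec50` on the T1 potency (the fade ratios ride on
#' it unchanged).
#'
#' @param patient Cohort row or [patient_covariates()].
#' @param base Population parameter set.
#' @export
patient_parameters <- function(patient, base = default_pkpd_parameters()) {
  pat <- as_patient(patient)
  cov <- patient_covariates(pat$sex, pat$age_y, pat$height_cm,
                            pat$weight_kg, pat$scr_mg_dl,
                            asian = isTRUE(pat$asian),
                            sevoflurane = isTRUE(pat$sevoflurane))
  p <- apply_covariates(base, cov)
  for (nm in c("cl_rb", "cl_sgx", "cl_cx")) p[[nm]] <- p[[nm]] * pat$m_cl
  for (nm in c("v1_rb", "v1_sgx", "v1_cx")) p[[nm]] <- p[[nm]] * pat$m_v1
  p$ec50_t1 <- p$ec50_t1 * pat$m_ec50
  validate_parameters(p)
  p
}
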