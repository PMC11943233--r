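#' Ideal body weight (Devine convention)
#'
#' Standard anesthesiology dosing weight: 50 kg (male) or 45.5 kg (female)
#' at 152.4 cm (5 ft), plus 2.3 kg per inch of height above that. Rocuronium
#' doses in the automated protocol are scaled by this weight.
#'
#' @param height_cm Body height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @param base Named base weights (kg) at 152.4 cm; override to use a
#'   different convention.
#' @return Ideal body weight in kg.
#' @export
#' @examples
#' ideal_body_weight(177.8, "male") # 73 kg
ideal_body_weight <- function(height_cm, sex,
                              base = c(male = 50, female = 45.5)) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(height_cm) || any(height_cm <= 0)) {
    stop("`height_cm` must be positive", call. = FALSE)
  }
  inches_over <- (height_cm - 152.4) / 2.54
  unname(base[[sex]] + 2.3 * inches_over)
}

#' Estimated creatinine clearance (Cockcroft-Gault)
#'
#' eCCr = (140 - age) * weight / (72 * SCr), multiplied by 0.85 for
#' females. This is the renal-function covariate that scales sugammadex
#' (and complex) clearance.
#'
#' @param age_y Age in years (< 140).
#' @param weight_kg Body weight in kg (> 0).
#' @param scr_mg_dl Serum creatinine in mg/dL (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Estimated creatinine clearance in mL/min.
#' @export
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male") # 100
cockcroft_gault <- function(age_y, weight_kg, scr_mg_dl, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(age_y >= 140)) stop("`age_y` must be < 140", call. = FALSE)
  if (any(weight_kg <= 0)) stop("`weight_kg` must be positive", call. = FALSE)
  if (any(scr_mg_dl <= 0)) stop("`scr_mg_dl` must be positive", call. = FALSE)
  eccr <- (140 - age_y) * weight_kg / (72 * scr_mg_dl)
  if (sex == "female") eccr <- eccr * 0.85
  eccr
}

#' Invert Cockcroft-Gault for serum creatinine
#'
#' Returns the serum creatinine (mg/dL) that yields a target eCCr for the
#' given demographics. Used by the cohort generator, which samples the
#' eCCr distribution directly and back-solves creatinine.
#'
#' @inheritParams cockcroft_gault
#' @param eccr_ml_min Target creatinine clearance in mL/min (> 0).
#' @export
cockcroft_gault_inverse <- function(age_y, weight_kg, eccr_ml_min, sex) {
  sex <- match.arg(sex, c("male", "female"))
  if (any(eccr_ml_min <= 0)) stop("`eccr_ml_min` must be positive", call. = FALSE)
  if (any(age_y >= 140)) stop("`age_y` must be < 140", call. = FALSE)
  scr <- (140 - age_y) * weight_kg / (72 * eccr_ml_min)
  if (sex == "female") scr <- scr * 0.85
  scr
}

#' Patient covariates
#'
#' Constructor and validator for the demographic/physiologic inputs of the
#' covariate model.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_y Age in years (study inclusion: >= 20).
#' @param height_cm Height in cm.
#' @param weight_kg Actual body weight in kg.
#' @param scr_mg_dl Serum creatinine in mg/dL.
#' @param asian Logical; the population the model parameters refer to.
#' @param sevoflurane Logical; always `FALSE` under total intravenous
#'   anesthesia. The flag is carried but has no effect by default.
#' @return A `patient_covariates` list with a derived `bmi` field.
#' @export
patient_covariates <- function(sex, age_y, height_cm, weight_kg, scr_mg_dl,
                               asian = TRUE, sevoflurane = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(age_y >= 20, height_cm > 0, weight_kg > 0, scr_mg_dl > 0)
  out <- list(
    sex = sex, age_y = age_y, height_cm = height_cm,
    weight_kg = weight_kg, scr_mg_dl = scr_mg_dl,
    asian = isTRUE(asian), sevoflurane = isTRUE(sevoflurane),
    bmi = weight_kg / (height_cm / 100)^2
  )
  class(out) <- "patient_covariates"
  out
}

#' Scale population parameters to one patient
#'
#' Applies multiplicative covariate scalings to the population-typical
#' parameter set: allometric size scaling of volumes and clearances,
#' renal-function (eCCr) scaling of sugammadex/complex (and partially
#' rocuronium) clearance, an age effect on rocuronium clearance and
#' potency, and a non-Asian potency factor. Every scaling is a power
#' function `(x / x_ref)^theta`, continuous and monotone, with reference
#' values and exponents held in the parameter set itself; at the reference
#' covariate vector the output equals the input.
#'
#' @param base A parameter set from [default_pkpd_parameters()].
#' @param cov A [patient_covariates()] object.
#' @return The scaled parameter set.
#' @export
apply_covariates <- function(base, cov) {
  stopifnot(inherits(cov, "patient_covariates"))
  validate_parameters(base)
  p <- base
  eccr <- cockcroft_gault(cov$age_y, cov$weight_kg, cov$scr_mg_dl, cov$sex)

  fwv <- (cov$weight_kg / p$ref_weight)^p$wt_exp_v
  fwc <- (cov$weight_kg / p$ref_weight)^p$wt_exp_cl
  fren <- (eccr / p$ref_eccr)
  fage <- (cov$age_y / p$ref_age)

  for (nm in c("v1_rb", "v2_rb", "v1_sgx", "v2_sgx", "v1_cx", "v2_cx")) {
    p[[nm]] <- p[[nm]] * fwv
  }
  for (nm in c("q_rb", "q_sgx", "q_cx")) p[[nm]] <- p[[nm]] * fwc
  p$cl_rb <- p$cl_rb * fwc * fren^p$eccr_exp_rb * fage^p$age_exp_cl_rb
  p$cl_sgx <- p$cl_sgx * fwc * fren^p$eccr_exp_sgx
  p$cl_cx <- p$cl_cx * fwc * fren^p$eccr_exp_sgx
  p$ec50_t1 <- p$ec50_t1 * fage^p$age_exp_ec50
  if (!cov$asian) p$ec50_t1 <- p$ec50_t1 * p$nonasian_ec50
  validate_parameters(p)
  p
}

#' Reference covariate vector
#'
#' The cohort-typical patient at which [apply_covariates()] is the
#' identity: Table-level mean age, height and weight, with serum
#' creatinine back-solved so eCCr equals the reference exactly.
#'
#' @param params Parameter set supplying the reference values.
#' @export
reference_covariates <- function(params = default_pkpd_parameters()) {
  height <- 159.0
  scr <- cockcroft_gault_inverse(params$ref_age, params$ref_weight,
                                 params$ref_eccr, "female")
  patient_covariates("female", params$ref_age, height, params$ref_weight,
                     scr, asian = TRUE)
}
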