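# Ten-year CVD risk score used for screening stratification: a simplified
# Cox-style score with documented, editable coefficients.

#' Default risk-score coefficients
#'
#' Coefficients of the simplified Cox-style 10-year CVD risk score used for
#' screening-band stratification: `risk = 1 - S0 ^ exp(lp)` with a linear
#' predictor over age, systolic blood pressure, total cholesterol, smoking
#' status, diabetes, body mass index and deprivation fifth, centred at a
#' reference profile. The coefficients are editable defaults chosen for
#' plausible direction and rough magnitude; the screening scenarios
#' recalibrate band membership during participant selection, so band
#' boundaries rather than clinical accuracy drive the simulation.
#'
#' @return list with `S0` (10-year baseline survival by sex), per-unit
#'   log-hazard coefficients and the reference profile `ref`.
#' @export
default_risk_coefficients <- function() {
  list(
    S0 = c(male = 0.935, female = 0.965),
    age = 0.070, sbp = 0.012, tchol = 0.15,
    smoker_current = 0.55, smoker_former = 0.15,
    diabetes = 0.60, bmi = 0.015, deprivation = 0.08,
    ref = list(age = 55, sbp = 130, tchol = 5.0, bmi = 27, imd = 3)
  )
}

#' Ten-year cardiovascular risk
#'
#' Cox-style 10-year first-event CVD risk, `1 - S0 ^ exp(lp)`, monotone
#' increasing in age, blood pressure, cholesterol, smoking, diabetes, body
#' mass index and deprivation for positive coefficients. Uses current (not
#' lagged) exposures: it represents risk as perceived at a screening visit.
#'
#' @param pop `data.table` with columns `age`, `sex`, `imd_fifth`, `sbp`,
#'   `tchol`, `smoking`, `diabetes`, `bmi` (one row per person), or a list
#'   with those fields.
#' @param coeffs coefficient list ([default_risk_coefficients()]).
#' @return numeric vector of risks in `[0, 1]`.
#' @export
ten_year_risk <- function(pop, coeffs = default_risk_coefficients()) {
  ref <- coeffs$ref
  lp <- coeffs$age * (pop$age - ref$age) +
    coeffs$sbp * (pop$sbp - ref$sbp) +
    coeffs$tchol * (pop$tchol - ref$tchol) +
    coeffs$smoker_current * (pop$smoking == "current") +
    coeffs$smoker_former * (pop$smoking == "former") +
    coeffs$diabetes * (pop$diabetes == 1) +
    coeffs$bmi * (pop$bmi - ref$bmi) +
    coeffs$deprivation * (pop$imd_fifth - ref$imd)
  s0 <- unname(coeffs$S0[ifelse(pop$sex == "male", "male", "female")])
  clamp(1 - s0^exp(lp), c(0, 1))
}

# Screening risk bands: below 10%, 10-20%, 20% or more.
risk_band <- function(risk, low = 0.10, high = 0.20) {
  cut(risk, c(-Inf, low, high, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}
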