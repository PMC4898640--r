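# Population specification: strata counts, exposure marginals with
# socioeconomic gradients, secular trend slopes, and bounds.

#' Construct a population specification
#'
#' A population specification describes the synthetic population to be
#' generated: how many persons fall in each age band x sex x deprivation
#' fifth stratum, the marginal distribution of every cardiovascular risk
#' factor (with age, sex and deprivation gradients expressed through linear
#' predictors), the annual secular trend slope of each factor, and hard
#' plausibility bounds.
#'
#' Each entry of `factors` is a list with a `family` field and
#' family-specific parameters:
#'
#' * `normal`: continuous factor; fields `mean` (named coefficients
#'   `intercept`, `age`, `male`, `imd` of a linear predictor evaluated at
#'   `age - 50`, a male indicator and `imd_fifth - 3`), `sd`, `slope`
#'   (units/year on the natural scale) and `bounds`.
#' * `binary`: 0/1 factor; fields `logit` (same coefficient names, on the
#'   log-odds scale) and `slope` (log-odds/year).
#' * `smoking`: three-level never/former/current status; fields
#'   `logit_current` (log-odds of current smoking), `logit_former`
#'   (log-odds of being a former smoker among non-current), `slope`
#'   (log-odds/year drift of current-smoking prevalence, usually negative)
#'   and `quit_years_mean` (mean years since quitting for former smokers).
#' * `binom7`: integer 0-7 days/week factor; fields `logit` (log-odds of an
#'   active day) and `slope` (log-odds/year).
#'
#' @param strata `data.table` (or data.frame) with columns `ageband`, `sex`,
#'   `imd_fifth`, `count`. Counts are relative weights; [build_population()]
#'   scales them to the requested population size.
#' @param factors named list of factor marginal specifications (see Details).
#'   The names must cover `bmi`, `sbp`, `tchol`, `diabetes`, `smoking`,
#'   `ets`, `fv_portions`, `pa_days`.
#' @param base_year first simulated calendar year (default 2011). Build-time
#'   exposures represent `base_year - 1` and lag buffers reach back a further
#'   five years.
#' @return an object of class `population_spec`.
#' @seealso [default_population_spec()], [build_population()]
#' @export
population_spec <- function(strata, factors, base_year = 2011L) {
  strata <- as.data.table(strata)
  need <- c("ageband", "sex", "imd_fifth", "count")
  if (!all(need %in% names(strata))) {
    config_error("strata", paste("missing columns:",
                                 paste(setdiff(need, names(strata)), collapse = ", ")))
  }
  if (any(strata$count < 0)) config_error("strata$count", "counts must be >= 0")
  if (!all(strata$sex %in% c("male", "female"))) {
    config_error("strata$sex", "levels must be 'male'/'female'")
  }
  if (!all(strata$imd_fifth %in% 1:5)) {
    config_error("strata$imd_fifth", "values must be integers 1..5")
  }
  required <- c("bmi", "sbp", "tchol", "diabetes", "smoking", "ets",
                "fv_portions", "pa_days")
  missing_f <- setdiff(required, names(factors))
  if (length(missing_f)) {
    config_error("factors", paste("missing factor(s):", paste(missing_f, collapse = ", ")))
  }
  for (nm in names(factors)) validate_factor_spec(nm, factors[[nm]])
  structure(
    list(strata = strata, factors = factors, base_year = as.integer(base_year)),
    class = "population_spec"
  )
}

validate_factor_spec <- function(name, f) {
  fam <- f$family %||% config_error(name, "no 'family' field")
  ok <- switch(fam,
    normal = {
      if (!is.numeric(f$sd) || f$sd < 0) config_error(paste0(name, "$sd"), "must be >= 0")
      if (is.null(f$mean)) config_error(paste0(name, "$mean"), "missing coefficients")
      if (!is.null(f$bounds) && f$bounds[1] > f$bounds[2]) {
        config_error(paste0(name, "$bounds"), "lo > hi")
      }
      TRUE
    },
    binary = {
      if (is.null(f$logit)) config_error(paste0(name, "$logit"), "missing coefficients")
      TRUE
    },
    smoking = {
      if (is.null(f$logit_current) || is.null(f$logit_former)) {
        config_error(name, "needs 'logit_current' and 'logit_former'")
      }
      TRUE
    },
    binom7 = {
      if (is.null(f$logit)) config_error(paste0(name, "$logit"), "missing coefficients")
      TRUE
    },
    config_error(paste0(name, "$family"), paste("unknown family", fam))
  )
  invisible(ok)
}

# Evaluate a named-coefficient linear predictor on person covariates.
linpred <- function(coefs, age, male, imd) {
  co <- function(nm) if (is.null(coefs[[nm]])) 0 else coefs[[nm]]
  co("intercept") + co("age") * (age - 50) + co("male") * male +
    co("imd") * (imd - 3)
}

#' England-like default population specification
#'
#' A synthetic-population specification with magnitudes resembling the
#' community-dwelling adult population of England around 2011: a five-year
#' age-band structure declining at older ages, equal sexes, equal 20%
#' deprivation fifths, continuous risk factors (body mass index, systolic
#' blood pressure, total cholesterol) with deprivation and age gradients,
#' categorical factors (diabetes, smoking status, environmental tobacco
#' smoke, fruit/vegetable portions, physical activity days) and linear
#' secular trends continuing the direction observed over 2001-12 (falling
#' blood pressure, cholesterol and smoking; rising body mass index and
#' diabetes). It is synthetic: it emulates survey-like structure without
#' reproducing any survey microdata.
#'
#' @return a [population_spec()] object.
#' @export
default_population_spec <- function() {
  bands <- age_band_labels()
  w <- c(1.00, 0.95, 1.02, 1.05, 0.97, 0.88, 0.80, 0.72, 0.55, 0.42, 0.30)
  strata <- CJ(ageband = bands, sex = c("female", "male"), imd_fifth = 1:5)
  strata[, count := w[match(ageband, bands)] / (2 * 5) * 1000]
  factors <- list(
    bmi = list(family = "normal",
               mean = list(intercept = 27.1, age = 0.030, male = 0.20, imd = 0.35),
               sd = 4.6, slope = 0.06, bounds = c(16, 70)),
    sbp = list(family = "normal",
               mean = list(intercept = 123.5, age = 0.48, male = 3.5, imd = 0.70),
               sd = 14.5, slope = -0.45, bounds = c(80, 220)),
    tchol = list(family = "normal",
                 mean = list(intercept = 5.45, age = 0.012, male = 0.05, imd = 0.04),
                 sd = 1.05, slope = -0.03, bounds = c(2, 12)),
    diabetes = list(family = "binary",
                    logit = list(intercept = -3.5, age = 0.060, male = 0.25, imd = 0.18),
                    slope = 0.03),
    smoking = list(family = "smoking",
                   logit_current = list(intercept = -1.45, age = -0.018, male = 0.12, imd = 0.33),
                   logit_former = list(intercept = -0.90, age = 0.035, male = 0.30, imd = -0.05),
                   slope = -0.035, quit_years_mean = 12),
    ets = list(family = "binary",
               logit = list(intercept = -1.60, age = 0.0, male = 0.05, imd = 0.28),
               slope = -0.04),
    fv_portions = list(family = "normal",
                       mean = list(intercept = 3.90, age = 0.012, male = -0.25, imd = -0.28),
                       sd = 2.1, slope = 0.015, bounds = c(0, 12)),
    pa_days = list(family = "binom7",
                   logit = list(intercept = -0.35, age = -0.012, male = 0.18, imd = -0.10),
                   slope = 0)
  )
  population_spec(strata, factors, base_year = 2011L)
}
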