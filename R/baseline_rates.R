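# Baseline epidemiology: incidence, case fatality (with annual relative
# improvement and a deprivation gradient), other-cause mortality, and the
# calibration tying configured rates to the multiplicative risk model.

#' Default baseline rate tables
#'
#' England-like baseline disease rates shipped as editable defaults:
#' first-ever CHD and stroke incidence rising log-linearly with age
#' (Gompertz shape, higher in men), first-year case fatality rising with age
#' (higher for stroke), and other-cause (non-CVD) mortality from a
#' Gompertz-shaped life-table analogue. Case fatality improves by 3%
#' (relative) annually from the reference year and carries a deprivation
#' gradient (multiplier per fifth away from the middle fifth) so more
#' deprived persons experience worse survival. Relative risks act on
#' incidence only, never on case fatality.
#'
#' @param base_year reference calendar year for the case-fatality decline
#'   (default 2011).
#' @return list with `incidence`, `case_fatality` and `other_mortality`
#'   `data.table`s plus scalars `cf_decline` (0.03), `cf_ses_gradient`
#'   (1.05), `prevalent_cf_mult` (0.35) and `base_year`.
#' @export
default_baseline_rates <- function(base_year = 2011L) {
  bands <- age_band_labels()
  mid <- seq(32, 82, 5)
  grid <- CJ(ageband = bands, sex = c("female", "male"))
  grid[, mid := mid[match(ageband, bands)]]
  inc <- rbindlist(list(
    grid[, .(disease = "chd", ageband, sex,
             rate = 2.65e-4 * exp(0.080 * (mid - 32)) *
               ifelse(sex == "male", 1, 0.55))],
    grid[, .(disease = "stroke", ageband, sex,
             rate = 1.25e-4 * exp(0.090 * (mid - 32)) *
               ifelse(sex == "male", 1, 0.80))]
  ))
  cfat <- rbindlist(list(
    grid[, .(disease = "chd", ageband, sex,
             cf = plogis(-2.6 + 0.065 * (mid - 60)) *
               ifelse(sex == "male", 1, 0.95))],
    grid[, .(disease = "stroke", ageband, sex,
             cf = plogis(-2.0 + 0.070 * (mid - 60)) *
               ifelse(sex == "male", 1, 1.00))]
  ))
  oth <- grid[, .(ageband, sex,
                  rate = 6e-4 * exp(0.088 * (mid - 32)) *
                    ifelse(sex == "male", 1.25, 1))]
  list(incidence = inc, case_fatality = cfat, other_mortality = oth,
       cf_decline = 0.03, cf_ses_gradient = 1.05, prevalent_cf_mult = 0.35,
       base_year = as.integer(base_year))
}

#' Calibrate the baseline event probability to a target rate
#'
#' Under the multiplicative model each person's annual event probability is
#' `p0 * rr`. Given the configured stratum incidence rate and the combined
#' relative risks of the stratum's population, the baseline probability that
#' reproduces the configured rate in expectation is
#' `p0 = target_rate / mean(rr)`, so that `mean(p0 * rr) = target_rate`
#' exactly. If `p0 * max(rr)` would exceed 1, `p0` is capped at
#' `1 / max(rr)` with a warning.
#'
#' @param target_rate configured annual rate (per person-year, in `[0, 1]`).
#' @param rr_values combined relative risks of the stratum population
#'   (non-empty, positive).
#' @return baseline probability `p0`.
#' @export
calibrate_baseline_probability <- function(target_rate, rr_values) {
  if (length(rr_values) == 0 || all(is.na(rr_values))) {
    stop("rr_values must be non-empty", call. = FALSE)
  }
  stopifnot(target_rate >= 0, target_rate <= 1)
  p0 <- target_rate / mean(rr_values, na.rm = TRUE)
  mx <- max(rr_values, na.rm = TRUE)
  if (p0 * mx > 1) {
    warning(sprintf("baseline probability capped: p0 * max(rr) = %.3f > 1",
                    p0 * mx), call. = FALSE)
    p0 <- 1 / mx
  }
  p0
}

#' Case fatality by age, sex, deprivation and calendar year
#'
#' First-year case fatality declines by `cf_decline` (default 3%) relatively
#' per calendar year from the reference year, and carries a deprivation
#' gradient: `cf0 * (1 - cf_decline)^(year - year0) *
#' cf_ses_gradient^(imd_fifth - 3)`, clamped to `[0, 1]`.
#'
#' @param age ages in years (vectorised).
#' @param sex `"male"`/`"female"` (vectorised).
#' @param imd_fifth deprivation fifth 1 (least) to 5 (most deprived).
#' @param disease `"chd"` or `"stroke"`.
#' @param year calendar year (>= reference year).
#' @param rates baseline rates list ([default_baseline_rates()]).
#' @return case-fatality probabilities.
#' @export
case_fatality <- function(age, sex, imd_fifth, disease, year, rates) {
  dis <- disease
  tab <- rates$case_fatality[which(rates$case_fatality[["disease"]] == dis)]
  key <- paste(age_band(age), sex)
  cf0 <- tab$cf[match(key, paste(tab$ageband, tab$sex))]
  out <- cf0 * (1 - rates$cf_decline)^(year - rates$base_year) *
    rates$cf_ses_gradient^(imd_fifth - 3)
  clamp(out, c(0, 1))
}

# Stratum lookup of a rate table (incidence or other mortality).
rate_lookup <- function(tab, age, sex) {
  key <- paste(age_band(age), sex)
  tab$rate[match(key, paste(tab$ageband, tab$sex))]
}

#' Annual event probabilities for each person
#'
#' Converts the five-year-lagged exposure profile into this year's
#' probabilities of first-ever CHD incidence, first-ever stroke incidence,
#' death from CHD, death from stroke, and death from any other cause.
#' Incidence is `p0 * combined_rr` with `p0` calibrated per age band x sex
#' (see [calibrate_baseline_probability()]); persons who already carry a
#' first-ever disease flag have zero incidence probability for that disease.
#' Disease-death probability is incidence x case fatality for disease-free
#' persons and `case fatality x prevalent_cf_mult` for prevalent cases
#' (annual excess mortality). Case fatality is unaffected by risk factors.
#'
#' @param pop population `data.table` (alive persons).
#' @param rates baseline rates ([default_baseline_rates()]).
#' @param rr_table relative-risk table.
#' @param year calendar year.
#' @param p0 optional pre-calibrated baseline probabilities: `data.table`
#'   with columns `disease`, `ageband`, `sex`, `prob0`. When absent,
#'   calibrated on `pop` itself.
#' @return `data.table` with columns `chd_inc`, `stroke_inc`, `chd_death`,
#'   `stroke_death`, `other_death`, plus the combined relative risks
#'   `rr_chd`, `rr_stroke`; all probabilities in `[0, 1]`.
#' @export
annual_event_probabilities <- function(pop, rates, rr_table, year, p0 = NULL) {
  rr_chd <- combined_rr(pop, rr_table, "chd")
  rr_str <- combined_rr(pop, rr_table, "stroke")
  if (is.null(p0)) p0 <- calibrate_p0(pop, rates, rr_chd, rr_str)
  key <- paste(age_band(pop$age), pop$sex)
  dis_col <- p0[["disease"]]
  p0c <- p0[which(dis_col == "chd")]
  p0s <- p0[which(dis_col == "stroke")]
  base_c <- p0c$prob0[match(key, paste(p0c$ageband, p0c$sex))]
  base_s <- p0s$prob0[match(key, paste(p0s$ageband, p0s$sex))]
  chd_inc <- ifelse(pop$chd, 0, clamp(base_c * rr_chd, c(0, 1)))
  stroke_inc <- ifelse(pop$stroke, 0, clamp(base_s * rr_str, c(0, 1)))
  cf_c <- case_fatality(pop$age, pop$sex, pop$imd_fifth, "chd", year, rates)
  cf_s <- case_fatality(pop$age, pop$sex, pop$imd_fifth, "stroke", year, rates)
  chd_death <- ifelse(pop$chd, cf_c * rates$prevalent_cf_mult, chd_inc * cf_c)
  stroke_death <- ifelse(pop$stroke, cf_s * rates$prevalent_cf_mult,
                         stroke_inc * cf_s)
  other_death <- clamp(rate_lookup(rates$other_mortality, pop$age, pop$sex) *
                         rates$cf_ses_gradient^(pop$imd_fifth - 3), c(0, 1))
  data.table(chd_inc = chd_inc, stroke_inc = stroke_inc,
             chd_death = clamp(chd_death, c(0, 1)),
             stroke_death = clamp(stroke_death, c(0, 1)),
             other_death = other_death,
             rr_chd = rr_chd, rr_stroke = rr_str)
}

# Calibrate p0 per disease x age band x sex against the population's
# combined relative risks (done once per iteration, on the first simulated
# year's population, and reused across scenarios and years).
calibrate_p0 <- function(pop, rates, rr_chd = NULL, rr_str = NULL,
                         rr_table = NULL) {
  if (is.null(rr_chd)) rr_chd <- combined_rr(pop, rr_table, "chd")
  if (is.null(rr_str)) rr_str <- combined_rr(pop, rr_table, "stroke")
  dt <- data.table(ageband = age_band(pop$age), sex = pop$sex,
                   rr_chd = rr_chd, rr_str = rr_str)
  out <- list()
  for (dis in c("chd", "stroke")) {
    inc <- rates$incidence[rates$incidence$disease == dis]
    rrcol <- if (dis == "chd") "rr_chd" else "rr_str"
    agg <- dt[, .(mean_rr = mean(.SD[[rrcol]]), max_rr = max(.SD[[rrcol]])),
              by = .(ageband, sex)]
    # strata present in the rate table but absent from this population get
    # the population-wide mean/max relative risk
    agg <- merge(agg, inc, by = c("ageband", "sex"), all.y = TRUE)
    agg[is.na(mean_rr), `:=`(mean_rr = mean(dt[[rrcol]]),
                             max_rr = max(dt[[rrcol]]))]
    agg[, prob0 := rate / mean_rr]
    capped <- agg$prob0 * agg$max_rr > 1
    if (any(capped)) {
      warning("baseline probability capped in ", sum(capped), " strata",
              call. = FALSE)
      agg[capped, prob0 := 1 / max_rr]
    }
    out[[dis]] <- agg[, .(disease = dis, ageband, sex, prob0)]
  }
  rbindlist(out)
}
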