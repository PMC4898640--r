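# Synthetic population: generation, secular trend projection, annual
# exposure advancement with a five-year lag buffer.

# Exposure columns carried in the five-year lag buffer, with the short
# prefixes used for the lag columns (<prefix>_l1 .. <prefix>_l5; _l5 is the
# value five years ago and is the profile that drives incidence).
LAG_FACTORS <- c(bmi = "bmi", sbp = "sbp", tchol = "tchol",
                 fv_portions = "fv", pa_days = "pa",
                 diabetes = "dm", smoking = "smk", ets = "ets")

lag_cols <- function(prefix) paste0(prefix, "_l", 1:5)

# Draw one exposure profile per row of (age, male, imd) at trend offset
# t_offset years after the specification's reference year (base_year - 1).
draw_exposures <- function(spec, age, male, imd, t_offset = 0) {
  n <- length(age)
  out <- data.table(row_id = seq_len(n))
  fs <- spec$factors
  for (nm in c("bmi", "sbp", "tchol", "fv_portions")) {
    f <- fs[[nm]]
    mu <- linpred(f$mean, age, male, imd) + f$slope * t_offset
    out[[nm]] <- clamp(rnorm(n, mu, f$sd), f$bounds)
  }
  for (nm in c("diabetes", "ets")) {
    f <- fs[[nm]]
    p <- plogis(linpred(f$logit, age, male, imd) + f$slope * t_offset)
    out[[nm]] <- as.integer(runif(n) < p)
  }
  f <- fs$smoking
  p_cur <- plogis(linpred(f$logit_current, age, male, imd) + f$slope * t_offset)
  p_fmr <- plogis(linpred(f$logit_former, age, male, imd))
  u1 <- runif(n); u2 <- runif(n)
  smoking <- ifelse(u1 < p_cur, "current", ifelse(u2 < p_fmr, "former", "never"))
  out[["smoking"]] <- smoking
  ysq <- rep(NA_real_, n)
  fmr <- smoking == "former"
  if (any(fmr)) {
    ysq[fmr] <- clamp(round(rexp(sum(fmr), 1 / (f$quit_years_mean %||% 12))),
                      c(0, Inf))
    ysq[fmr] <- pmin(ysq[fmr], pmax(age[fmr] - 20, 0))
  }
  out[["years_since_quit"]] <- ysq
  f <- fs$pa_days
  p <- plogis(linpred(f$logit, age, male, imd) + f$slope * t_offset)
  out[["pa_days"]] <- rbinom(n, 7L, p)
  out[, row_id := NULL]
  out
}

# Initialise the lag buffer by back-casting the secular trend 1..5 years
# behind the current exposure values. Categorical factors are carried back
# unchanged (their trends act through prevalence shifts, not individual
# histories).
init_lag_buffer <- function(pop, spec) {
  for (nm in names(LAG_FACTORS)) {
    pre <- LAG_FACTORS[[nm]]
    f <- spec$factors[[nm]]
    for (k in 1:5) {
      col <- paste0(pre, "_l", k)
      if (nm %in% c("bmi", "sbp", "tchol", "fv_portions")) {
        set(pop, j = col, value = clamp(pop[[nm]] - k * f$slope, f$bounds))
      } else {
        set(pop, j = col, value = pop[[nm]])
      }
    }
  }
  invisible(pop)
}

# Scenario/vital state columns shared by build_population and new_entrants.
init_state_columns <- function(pop, entry_year) {
  pop[, `:=`(
    chd = FALSE, stroke = FALSE, alive = TRUE,
    screened = FALSE, high_risk = FALSE,
    on_statin = FALSE, on_antihtn = FALSE,
    tx_year = NA_integer_, persist_ok = NA,
    cess_quit = FALSE, fv_resp = FALSE,
    entry_year = as.integer(entry_year)
  )]
  invisible(pop)
}

#' Generate a synthetic population
#'
#' Samples `n` persons from the stratum weights of a [population_spec()]
#' (multinomial over age band x sex x deprivation fifth), draws each risk
#' factor from its stratum-specific marginal, and initialises the five-year
#' exposure lag buffer by back-casting the secular trends. Exposure values
#' represent the year before the first simulated year (`base_year - 1`), so
#' that in simulated year y incidence is driven by exposures from exactly
#' y - 5.
#'
#' @param spec a [population_spec()].
#' @param n number of persons (> 0).
#' @param seed integer seed; identical `(spec, n, seed)` return identical
#'   populations.
#' @return a `data.table`, one row per person, with demographics, current
#'   exposures, lag-buffer columns (`*_l1` .. `*_l5`), first-ever disease
#'   flags and intervention-state columns.
#' @export
build_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n > 0)
  set.seed(as.integer(seed))
  strata <- spec$strata
  probs <- strata$count / sum(strata$count)
  idx <- sample.int(nrow(strata), n, replace = TRUE, prob = probs)
  lo <- as.integer(sub("-.*", "", strata$ageband[idx]))
  pop <- data.table(
    id = seq_len(n),
    age = lo + sample(0:4, n, replace = TRUE),
    sex = strata$sex[idx],
    imd_fifth = as.integer(strata$imd_fifth[idx])
  )
  exp_dt <- draw_exposures(spec, pop$age, as.numeric(pop$sex == "male"),
                           pop$imd_fifth, t_offset = 0)
  pop <- cbind(pop, exp_dt)
  init_lag_buffer(pop, spec)
  init_state_columns(pop, spec$base_year)
  setkey(pop, id)
  pop[]
}

#' Project a risk-factor value along its linear secular trend
#'
#' Continuous factors follow a linear trend on the natural scale:
#' `value + slope * years`, clamped to `bounds`. Negative `years` back-casts
#' (used to initialise lag buffers); when no clamping occurs the projection
#' is exactly invertible.
#'
#' @param value current factor value(s).
#' @param slope annual change in factor units/year.
#' @param years number of years to project (may be negative).
#' @param bounds optional `c(lo, hi)` clamp range.
#' @return projected value(s).
#' @export
project_trend <- function(value, slope, years, bounds = NULL) {
  clamp(value + slope * years, bounds)
}

# Annual prevalence-shift transition probability for a binary factor whose
# prevalence follows a linear log-odds trend. Returns per-person transition
# probabilities: a positive slope moves 0 -> 1, a negative slope 1 -> 0.
prevalence_shift_prob <- function(lp, slope, t_from) {
  p0 <- plogis(lp + slope * t_from)
  p1 <- plogis(lp + slope * (t_from + 1))
  if_up <- (p1 - p0) / pmax(1 - p0, 1e-12)
  if_down <- (p0 - p1) / pmax(p0, 1e-12)
  list(up = pmax(if_up, 0), down = pmax(if_down, 0))
}

#' Advance exposures by one simulated year
#'
#' Pushes the current exposure profile onto the five-year lag buffer
#' (dropping the oldest entry) and then applies one year of secular trend:
#' linear on the natural scale for continuous factors and stochastic
#' prevalence-shift transitions on the log-odds scale for categorical
#' factors. Dead persons are left untouched.
#'
#' The engine passes `effective` overrides so that the values entering the
#' lag buffer reflect treatment overlays (statin/antihypertensive effects,
#' population-wide blood-pressure shifts) without mutating the underlying
#' trend trajectory, and `bmi_slope_mult` to damp the BMI trend under the
#' population-wide policy.
#'
#' @param pop population `data.table` (modified by reference when
#'   `in_place = TRUE`, the engine path; copied otherwise).
#' @param spec the [population_spec()].
#' @param year calendar year being entered; exposures move from `year - 1`
#'   to `year` values.
#' @param effective optional named list of numeric vectors (`sbp`, `tchol`,
#'   ...) to push into the buffer in place of the stored values.
#' @param u optional matrix of per-person uniforms with columns
#'   `dm`, `smk`, `ets` (common-random-number path); drawn internally when
#'   absent.
#' @param bmi_slope_mult multiplier on the BMI trend slope (default 1).
#' @param in_place modify `pop` by reference.
#' @return the advanced population `data.table`.
#' @export
advance_exposures <- function(pop, spec, year, effective = NULL, u = NULL,
                              bmi_slope_mult = 1, in_place = FALSE) {
  if (!in_place) pop <- copy(pop)
  al <- pop$alive
  if (!any(al)) return(pop)
  n <- nrow(pop)
  if (is.null(u)) {
    u <- cbind(dm = runif(n), smk = runif(n), ets = runif(n))
  }
  # 1. push current (year - 1) profile onto the buffer
  for (nm in names(LAG_FACTORS)) {
    pre <- LAG_FACTORS[[nm]]
    for (k in 5:2) {
      set(pop, which(al), paste0(pre, "_l", k),
          pop[[paste0(pre, "_l", k - 1)]][al])
    }
    cur <- if (!is.null(effective[[nm]])) effective[[nm]] else pop[[nm]]
    set(pop, which(al), paste0(pre, "_l1"), cur[al])
  }
  # 2. one year of trend on the stored (natural) values
  idx <- which(al)
  age <- pop$age[idx]
  male <- as.numeric(pop$sex[idx] == "male")
  imd <- pop$imd_fifth[idx]
  t_from <- (year - 1) - (spec$base_year - 1)
  for (nm in c("bmi", "sbp", "tchol", "fv_portions")) {
    f <- spec$factors[[nm]]
    slope <- f$slope * if (nm == "bmi") bmi_slope_mult else 1
    set(pop, idx, nm, clamp(pop[[nm]][idx] + slope, f$bounds))
  }
  for (nm in c("diabetes", "ets")) {
    f <- spec$factors[[nm]]
    q <- prevalence_shift_prob(linpred(f$logit, age, male, imd), f$slope, t_from)
    cur <- pop[[nm]][idx]
    uu <- u[idx, if (nm == "diabetes") "dm" else "ets"]
    nxt <- ifelse(cur == 0L & uu < q$up, 1L,
                  ifelse(cur == 1L & uu < q$down, 0L, cur))
    set(pop, idx, nm, as.integer(nxt))
  }
  # former smokers accumulate years since quitting, then secular quitting
  fmr <- idx[pop$smoking[idx] == "former"]
  if (length(fmr)) set(pop, fmr, "years_since_quit",
                       pop$years_since_quit[fmr] + 1)
  f <- spec$factors$smoking
  if (f$slope < 0) {
    qs <- prevalence_shift_prob(linpred(f$logit_current, age, male, imd),
                                f$slope, t_from)
    quit <- idx[pop$smoking[idx] == "current" & u[idx, "smk"] < qs$down]
    if (length(quit)) {
      set(pop, quit, "smoking", "former")
      set(pop, quit, "years_since_quit", 0)
    }
  }
  pop
}

# New 30-year-old entrants for one simulated year, with exposures projected
# to the current year and lag buffers back-cast. Entry into an open cohort:
# the number and composition depend only on the specification, never on the
# scenario, preserving common random numbers across scenarios.
new_entrants <- function(spec, n, year, seed, id_start) {
  if (n <= 0) return(NULL)
  set.seed(as.integer(seed))
  strata <- spec$strata[ageband == age_band_labels()[1]]
  probs <- strata$count / sum(strata$count)
  idx <- sample.int(nrow(strata), n, replace = TRUE, prob = probs)
  pop <- data.table(
    id = id_start + seq_len(n) - 1L,
    age = 30L,
    sex = strata$sex[idx],
    imd_fifth = as.integer(strata$imd_fifth[idx])
  )
  t_offset <- year - (spec$base_year - 1)
  exp_dt <- draw_exposures(spec, pop$age, as.numeric(pop$sex == "male"),
                           pop$imd_fifth, t_offset = t_offset)
  pop <- cbind(pop, exp_dt)
  init_lag_buffer(pop, spec)
  init_state_columns(pop, year)
  pop
}
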