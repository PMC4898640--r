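# Shared fixtures: all built in code at test time.

library(data.table)

# A single-stratum specification (one age band, one sex, one fifth) with
# optional overrides of factor fields, e.g. zero slopes for trend tests.
single_stratum_spec <- function(ageband = "50-54", sex = "male", imd = 3,
                                overrides = list()) {
  spec <- default_population_spec()
  strata <- spec$strata[0]
  strata <- data.table(ageband = ageband, sex = sex,
                       imd_fifth = as.integer(imd), count = 1)
  factors <- spec$factors
  for (nm in names(overrides)) {
    factors[[nm]] <- utils::modifyList(factors[[nm]], overrides[[nm]])
  }
  population_spec(strata, factors, base_year = spec$base_year)
}

zero_slope_overrides <- function() {
  list(bmi = list(slope = 0), sbp = list(slope = 0), tchol = list(slope = 0),
       fv_portions = list(slope = 0), diabetes = list(slope = 0),
       smoking = list(slope = 0), ets = list(slope = 0),
       pa_days = list(slope = 0))
}

# Exposure profile rows at the default relative-risk reference levels
# (combined relative risk exactly 1), with optional per-column overrides.
ref_profile <- function(n = 1, ...) {
  out <- data.table(
    bmi = rep(23, n), sbp = 115, tchol = 3.8, fv_portions = 5,
    pa_days = 5L, diabetes = 0L, smoking = "never",
    years_since_quit = NA_real_, ets = 0L
  )
  ov <- list(...)
  for (nm in names(ov)) set(out, j = nm, value = ov[[nm]])
  out
}

# A minimal population at the reference profile (lag buffer = current
# values), for unit tests of probabilities and the engine.
ref_pop <- function(n = 1, age = 55L, sex = "male", imd = 3L, ...) {
  pop <- copy(cbind(
    data.table(id = seq_len(n), age = as.integer(age), sex = sex,
               imd_fifth = as.integer(imd)),
    ref_profile(n, ...)
  ))
  for (nm in names(cvdmicrosim:::LAG_FACTORS)) {
    pre <- cvdmicrosim:::LAG_FACTORS[[nm]]
    for (k in 1:5) set(pop, j = paste0(pre, "_l", k), value = pop[[nm]])
  }
  pop[, `:=`(chd = FALSE, stroke = FALSE, alive = TRUE, screened = FALSE,
             high_risk = FALSE, on_statin = FALSE, on_antihtn = FALSE,
             tx_year = NA_integer_, persist_ok = NA, cess_quit = FALSE,
             fv_resp = FALSE, entry_year = 2011L)]
  pop[]
}

# Tiny deterministic results cube for outcome-metric tests: one outcome
# count per (iteration, year, fifth), same value in every cell unless a
# delta table is supplied.
toy_cube <- function(counts_by_fifth, iterations = 1, years = 2016:2017,
                     outcome = "chd_case") {
  cells <- CJ(iteration = seq_len(iterations), year = years, imd_fifth = 1:5)
  cells[, `:=`(ageband = "50-54", sex = "male", outcome = outcome,
               count = counts_by_fifth[imd_fifth])]
  cells[]
}

expect_cube_equal <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  setindex(a, NULL); setindex(b, NULL)
  keys <- intersect(c("scenario", "iteration", "year", "ageband", "sex",
                      "imd_fifth", "outcome"), names(a))
  setorderv(a, keys); setorderv(b, keys)
  expect_equal(as.data.frame(a), as.data.frame(b))
}
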