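# Relative-risk specification and the multiplicative combined relative risk
# linking lagged exposures to first-ever CHD and stroke incidence.

#' Default relative-risk table
#'
#' Literature-plausible per-exposure relative risks for coronary heart
#' disease and stroke, shipped as editable defaults. Continuous exposures
#' carry a reference level and a unit size (`per`): the contribution is
#' `rr ^ ((x - ref) / per)`, so exposure below reference is protective; the
#' per-factor contribution is floored (default 0.5) to avoid implausible
#' extrapolation. Categorical exposures carry one row per non-reference
#' level. `ci_lo`/`ci_hi` are 95% interval bounds used for second-order
#' Monte Carlo sampling via [sample_relative_risks()].
#'
#' @return `data.table` with columns `exposure`, `disease`, `type`, `level`,
#'   `ref`, `per`, `rr`, `ci_lo`, `ci_hi`, `floor`.
#' @export
default_relative_risks <- function() {
  cont <- function(exposure, disease, ref, per, rr, lo, hi)
    data.table(exposure = exposure, disease = disease, type = "continuous",
               level = NA_character_, ref = ref, per = per,
               rr = rr, ci_lo = lo, ci_hi = hi, floor = 0.5)
  cat_ <- function(exposure, disease, level, rr, lo, hi)
    data.table(exposure = exposure, disease = disease, type = "categorical",
               level = level, ref = NA_real_, per = NA_real_,
               rr = rr, ci_lo = lo, ci_hi = hi, floor = 0.5)
  rbindlist(list(
    cont("bmi",         "chd",    23,  5, 1.25, 1.18, 1.32),
    cont("sbp",         "chd",   115, 20, 1.45, 1.35, 1.55),
    cont("tchol",       "chd",   3.8,  1, 1.35, 1.25, 1.45),
    cont("fv_portions", "chd",     5,  1, 0.96, 0.93, 0.99),
    cont("pa_days",     "chd",     5,  1, 0.97, 0.94, 1.00),
    cat_("diabetes",    "chd", "1",       1.90, 1.60, 2.20),
    cat_("smoking",     "chd", "current", 2.20, 1.90, 2.50),
    cat_("smoking",     "chd", "former",  1.25, 1.10, 1.40),
    cat_("ets",         "chd", "1",       1.25, 1.10, 1.40),
    cont("bmi",         "stroke",  23,  5, 1.15, 1.08, 1.22),
    cont("sbp",         "stroke", 115, 20, 1.60, 1.45, 1.75),
    cont("tchol",       "stroke", 3.8,  1, 1.08, 1.00, 1.16),
    cont("fv_portions", "stroke",   5,  1, 0.95, 0.92, 0.98),
    cont("pa_days",     "stroke",   5,  1, 0.97, 0.94, 1.00),
    cat_("diabetes",    "stroke", "1",       1.80, 1.50, 2.10),
    cat_("smoking",     "stroke", "current", 1.90, 1.60, 2.20),
    cat_("smoking",     "stroke", "former",  1.15, 1.00, 1.30),
    cat_("ets",         "stroke", "1",       1.25, 1.10, 1.40)
  ))
}

validate_rr_table <- function(rr_table) {
  rr_table <- as.data.table(rr_table)
  if (any(rr_table$rr <= 0)) config_error("rr", "relative risks must be > 0")
  bad <- rr_table[!(ci_lo <= rr & rr <= ci_hi)]
  if (nrow(bad)) {
    config_error(paste0("rr[", bad$exposure[1], ",", bad$disease[1], "]"),
                 "ci95 must bracket rr")
  }
  rr_table
}

#' Sample a relative-risk table for one second-order Monte Carlo iteration
#'
#' Draws each relative risk from a log-normal distribution centred on the
#' point estimate with standard deviation implied by the 95% interval
#' (`sd = (log(hi) - log(lo)) / (2 * 1.96)`), reflecting sampling error of
#' the published effect sizes.
#'
#' @param rr_table a relative-risk table ([default_relative_risks()]).
#' @param seed integer seed for the iteration's parameter stream.
#' @return a copy of `rr_table` with sampled `rr` values.
#' @export
sample_relative_risks <- function(rr_table, seed) {
  set.seed(as.integer(seed))
  out <- copy(as.data.table(rr_table))
  sdlog <- (log(out$ci_hi) - log(out$ci_lo)) / (2 * 1.96)
  out[, rr := exp(rnorm(.N, log(rr), sdlog))]
  # keep the interval invariant (ci brackets rr) for the sampled table
  out[, `:=`(ci_lo = pmin(ci_lo, rr), ci_hi = pmax(ci_hi, rr))]
  out
}

# Internal: pick the exposure columns for combined_rr. When lagged = TRUE
# the five-year-lagged (_l5) buffer columns drive the risk.
rr_input_cols <- function(lagged) {
  if (lagged) {
    c(bmi = "bmi_l5", sbp = "sbp_l5", tchol = "tchol_l5",
      fv_portions = "fv_l5", pa_days = "pa_l5",
      diabetes = "dm_l5", smoking = "smk_l5", ets = "ets_l5")
  } else {
    c(bmi = "bmi", sbp = "sbp", tchol = "tchol",
      fv_portions = "fv_portions", pa_days = "pa_days",
      diabetes = "diabetes", smoking = "smoking", ets = "ets")
  }
}

#' Combined multiplicative relative risk
#'
#' Multiplies per-exposure relative risks across the exposure profile:
#' continuous exposures contribute `rr ^ ((x - ref) / per)` (protective
#' below reference, floored per factor), categorical exposures contribute
#' the tabulated level-specific relative risk (reference levels contribute
#' 1). An optional age-attenuation schedule scales the log relative risk by
#' age band. The multiplicative combination across exposures is the standard
#' comparative-risk-assessment assumption.
#'
#' @param profile `data.table` of exposures; with `lagged = TRUE` (the
#'   engine path) the `*_l5` lag-buffer columns are used, otherwise the
#'   current-exposure columns.
#' @param rr_table relative-risk table.
#' @param disease `"chd"` or `"stroke"`.
#' @param age optional ages (needed only with `attenuation`).
#' @param attenuation optional named numeric vector of log-RR multipliers by
#'   age band.
#' @param lagged use the five-year-lagged profile (default `TRUE` when the
#'   lag columns are present).
#' @return numeric vector of combined relative risks (> 0).
#' @export
combined_rr <- function(profile, rr_table, disease, age = NULL,
                        attenuation = NULL,
                        lagged = "bmi_l5" %in% names(profile)) {
  rr_table <- validate_rr_table(rr_table)
  dis <- disease
  tab <- rr_table[which(rr_table[["disease"]] == dis)]
  if (!nrow(tab)) config_error("rr", paste("no rows for disease", disease))
  cols <- rr_input_cols(lagged)
  missing_exp <- setdiff(unique(tab$exposure), names(cols))
  if (length(missing_exp)) {
    config_error("rr$exposure", paste("unknown exposure(s):",
                                      paste(missing_exp, collapse = ", ")))
  }
  present <- names(cols)[cols %in% names(profile)]
  missing_from_spec <- setdiff(present, unique(tab$exposure))
  if (length(missing_from_spec)) {
    config_error("rr", paste("exposure(s) present in profile but missing",
                             "from the relative-risk table:",
                             paste(missing_from_spec, collapse = ", ")))
  }
  n <- nrow(profile)
  log_rr <- numeric(n)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i]
    col <- cols[[row$exposure]]
    x <- profile[[col]]
    if (row$type == "continuous") {
      contrib <- log(row$rr) * (x - row$ref) / row$per
      contrib <- pmax(contrib, log(row$floor))
    } else {
      hit <- as.character(x) == row$level
      contrib <- ifelse(hit, log(row$rr), 0)
    }
    log_rr <- log_rr + contrib
  }
  if (!is.null(attenuation)) {
    stopifnot(!is.null(age))
    mult <- attenuation[age_band(age)]
    mult[is.na(mult)] <- 1
    log_rr <- log_rr * mult
  }
  exp(log_rr)
}
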