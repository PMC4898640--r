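# Policy scenarios: screening (universal / concentrated), the structural
# population-wide intervention, their combination, and sensitivity variants.

#' Screening policy parameters
#'
#' Describes a risk-score-based screening and treatment programme. Defaults
#' follow the current primary-prevention health-check programme in England:
#' 50% uptake among eligible adults aged 40-74; a calibrated participant
#' risk mix of 70% below 10% ten-year risk, 25% between 10% and 20% and 5%
#' at 20% or more, with around 30% of participants older than 60; treatment
#' for those above a 10% risk threshold (statins offered to 24%/17% of the
#' high/intermediate band with cholesterol >= 5 mmol/L, antihypertensives to
#' 27%/20% with systolic pressure >= 135 mm Hg); 80% persistence beyond the
#' first year and 70% mean adherence; bariatric surgery above BMI 50
#' reducing BMI to 30; lifestyle counselling; and a 10% one-year smoking
#' cessation rate among high-risk smokers with population relapse rates.
#'
#' @param target_fifths deprivation fifths offered screening (1:5 universal;
#'   4:5 concentrated).
#' @param age_range eligible age range.
#' @param uptake screening uptake among eligible.
#' @param participant_risk_mix named fractions `c(low=, mid=, high=)`
#'   summing to 1, or `"match-eligible"` for simple random sampling.
#' @param share_over_60 target fraction of participants older than 60, or
#'   `"match-eligible"`.
#' @param treatment_threshold 10-year risk above which participants are
#'   treated.
#' @param statin_uptake,antihtn_uptake named prescription probabilities
#'   `c(high=, mid=)` for the >=20% and 10-20% risk bands.
#' @param tchol_threshold,sbp_threshold treatment eligibility thresholds
#'   (mmol/L, mm Hg).
#' @param persistence probability of persisting with drug treatment beyond
#'   the first year.
#' @param adherence mean adherence scaling drug effects while persisting.
#' @param statin_tchol_reduction,antihtn_sbp_reduction full-adherence drug
#'   effects (mmol/L, mm Hg); editable defaults.
#' @param bariatric_bmi_threshold,bariatric_bmi_target BMI above which
#'   bariatric surgery applies, and the post-surgery BMI.
#' @param lifestyle list of lifestyle-counselling parameters.
#' @param cessation_rate one-year cessation probability for high-risk
#'   current smokers.
#' @param uptake_ses_differential relative uptake multiplier for the most
#'   deprived fifth (0.9 in the sensitivity variant).
#' @return a `screening_policy` object.
#' @export
screening_policy <- function(target_fifths = 1:5,
                             age_range = c(40, 74),
                             uptake = 0.50,
                             participant_risk_mix = c(low = 0.70, mid = 0.25, high = 0.05),
                             share_over_60 = 0.30,
                             treatment_threshold = 0.10,
                             statin_uptake = c(high = 0.24, mid = 0.17),
                             antihtn_uptake = c(high = 0.27, mid = 0.20),
                             tchol_threshold = 5,
                             sbp_threshold = 135,
                             persistence = 0.80,
                             adherence = 0.70,
                             statin_tchol_reduction = 1.3,
                             antihtn_sbp_reduction = 10,
                             bariatric_bmi_threshold = 50,
                             bariatric_bmi_target = 30,
                             lifestyle = list(fv_threshold = 5, fv_prob = 0.5,
                                              pa_threshold = 5, pa_prob = 0.5,
                                              bmi_mult = 0.99),
                             cessation_rate = 0.10,
                             uptake_ses_differential = 1.0) {
  pol <- as.list(environment())
  fracs <- c(uptake, treatment_threshold, persistence, adherence,
             cessation_rate, statin_uptake, antihtn_uptake)
  if (any(fracs < 0 | fracs > 1)) {
    config_error("screening_policy", "all fractions must lie in [0, 1]")
  }
  if (is.numeric(participant_risk_mix)) {
    if (abs(sum(participant_risk_mix) - 1) > 1e-8) {
      config_error("participant_risk_mix", "must sum to 1")
    }
  } else if (!identical(participant_risk_mix, "match-eligible")) {
    config_error("participant_risk_mix", "numeric mix or 'match-eligible'")
  }
  structure(pol, class = "screening_policy")
}

#' Population-wide policy parameters
#'
#' A feasible structural intervention on diet and smoking: damping of the
#' annual BMI trend increment by 5% (sugary-drink taxation), a 0.8 mm Hg
#' population mean systolic blood-pressure reduction (mandatory salt
#' reformulation), one extra daily fruit/vegetable portion in half the
#' population (subsidies), and a 13% relative reduction in smoking
#' prevalence over five years (tobacco-control compliance). All effects are
#' phased in linearly with the diffusion schedule.
#'
#' @param bmi_trend_damping relative damping of the annual BMI trend
#'   increment at full coverage.
#' @param sbp_shift mean systolic pressure reduction (mm Hg) at full
#'   coverage.
#' @param fv_increase_share fraction of the population gaining a daily
#'   fruit/vegetable portion.
#' @param smoking_prev_reduction relative smoking-prevalence reduction
#'   achieved over `reduction_years`. Set to 0 for the diet-only
#'   sensitivity variant.
#' @param reduction_years years over which the smoking reduction accrues.
#' @return a `population_policy` object.
#' @export
population_policy <- function(bmi_trend_damping = 0.05,
                              sbp_shift = 0.8,
                              fv_increase_share = 0.5,
                              smoking_prev_reduction = 0.13,
                              reduction_years = 5) {
  if (bmi_trend_damping < 0 || bmi_trend_damping > 1) {
    config_error("bmi_trend_damping", "must lie in [0, 1]")
  }
  if (fv_increase_share < 0 || fv_increase_share > 1) {
    config_error("fv_increase_share", "must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "population_policy")
}

#' Scenario configuration
#'
#' Bundles an optional screening policy and an optional population-wide
#' policy with the common intervention assumptions: interventions begin in
#' `start_year` (2011) and diffuse linearly into the population over
#' `diffusion_years` (5). With both policies absent the scenario is the
#' baseline continuation of current trends.
#'
#' @param name scenario name.
#' @param screening optional [screening_policy()].
#' @param population_policy optional [population_policy()].
#' @param start_year first intervention year.
#' @param diffusion_years linear diffusion period.
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(name, screening = NULL, population_policy = NULL,
                            start_year = 2011L, diffusion_years = 5L) {
  if (!is.null(screening) && !inherits(screening, "screening_policy")) {
    config_error("screening", "must be a screening_policy")
  }
  if (!is.null(population_policy) &&
      !inherits(population_policy, "population_policy")) {
    config_error("population_policy", "must be a population_policy")
  }
  structure(list(name = name, screening = screening,
                 population_policy = population_policy,
                 start_year = as.integer(start_year),
                 diffusion_years = as.integer(diffusion_years)),
            class = "scenario_config")
}

#' @rdname canned_scenarios
#' @export
scenario_baseline <- function() scenario_config("baseline")

#' Canned policy scenarios
#'
#' The five core scenarios: continuation of current risk-factor trends
#' (baseline); universal screening with calibrated participant mix;
#' screening concentrated in the two most deprived fifths with a
#' match-eligible participant mix; the structural population-wide diet and
#' smoking intervention; and the combination of the population-wide
#' intervention with concentrated screening (proportionate universalism).
#'
#' @return a `scenario_config`.
#' @name canned_scenarios
NULL

#' @rdname canned_scenarios
#' @export
scenario_universal_screening <- function() {
  scenario_config("universal_screening", screening = screening_policy())
}

#' @rdname canned_scenarios
#' @export
scenario_concentrated_screening <- function() {
  scenario_config("concentrated_screening",
                  screening = screening_policy(
                    target_fifths = 4:5,
                    participant_risk_mix = "match-eligible",
                    share_over_60 = "match-eligible"))
}

#' @rdname canned_scenarios
#' @export
scenario_population_wide <- function() {
  scenario_config("population_wide", population_policy = population_policy())
}

#' @rdname canned_scenarios
#' @export
scenario_combined <- function() {
  scenario_config("combined",
                  screening = screening_policy(
                    target_fifths = 4:5,
                    participant_risk_mix = "match-eligible",
                    share_over_60 = "match-eligible"),
                  population_policy = population_policy())
}

#' Sensitivity-analysis scenario variants
#'
#' Three canned variations: universal screening with a 20% treatment
#' threshold; universal screening with 10% lower uptake in the most
#' deprived fifth; and a diet-only population-wide intervention with the
#' smoking component disabled.
#'
#' @return named list of three `scenario_config` objects.
#' @export
sensitivity_scenarios <- function() {
  list(
    universal_threshold20 = scenario_config(
      "universal_threshold20",
      screening = screening_policy(treatment_threshold = 0.20)),
    universal_uptake_differential = scenario_config(
      "universal_uptake_differential",
      screening = screening_policy(uptake_ses_differential = 0.9)),
    population_wide_diet_only = scenario_config(
      "population_wide_diet_only",
      population_policy = population_policy(smoking_prev_reduction = 0))
  )
}

#' Linear intervention diffusion coverage
#'
#' Interventions begin in `start_year` and are linearly diffused over
#' `diffusion_years`: coverage is 0 before the start year and
#' `clamp((year - start_year + 1) / diffusion_years, 0, 1)` thereafter, so
#' the first intervention year delivers 1/5 of the full effect under the
#' defaults (2011 -> 0.2, 2015 -> 1).
#'
#' @param year calendar year (vectorised).
#' @param start_year first intervention year.
#' @param diffusion_years diffusion period.
#' @return coverage fraction(s) in `[0, 1]`.
#' @export
coverage <- function(year, start_year = 2011, diffusion_years = 5) {
  ifelse(year < start_year, 0,
         clamp((year - start_year + 1) / diffusion_years, c(0, 1)))
}

#' Screening eligibility
#'
#' Eligible persons are aged within the policy age range, free of known
#' CVD (no first-ever CHD or stroke), free of diabetes, and live in a
#' targeted deprivation fifth. Exclusion morbidities that the model does not
#' carry (atrial fibrillation, rheumatoid arthritis, renal disease) are
#' approximated by a configurable per-person exclusion fraction, default 0.
#'
#' @param pop population `data.table`.
#' @param policy a [screening_policy()].
#' @return logical vector.
#' @export
screening_eligibility <- function(pop, policy) {
  pop$age >= policy$age_range[1] & pop$age <= policy$age_range[2] &
    !pop$chd & !pop$stroke & pop$diabetes == 0L &
    pop$imd_fifth %in% policy$target_fifths & pop$alive
}

# Iterative proportional fitting of a risk-band x over-60 target table to
# the eligible pool's joint support.
ipf_cell_targets <- function(joint, row_targets, col_targets,
                             tol = 1e-9, maxit = 200) {
  w <- joint * 1.0
  w[w == 0] <- 0
  for (i in seq_len(maxit)) {
    rs <- rowSums(w); rs[rs == 0] <- 1
    w <- w * (row_targets / rs)
    cs <- colSums(w); cs[cs == 0] <- 1
    w <- sweep(w, 2, col_targets / cs, "*")
    if (max(abs(rowSums(w) - row_targets)) < tol) break
  }
  w
}

#' Select screening participants
#'
#' Draws participants from the eligible pool. The participant count is
#' `uptake * coverage * |eligible|`. With an explicit participant risk mix,
#' participants are drawn by stratified sampling over (risk band x over-60)
#' cells whose target weights come from an iterative-proportional-fitting
#' step matching both the band mix (70/25/5 by default) and the over-60
#' share (30%) simultaneously; infeasible targets are met as closely as the
#' pool allows, with a warning. With `"match-eligible"`, participants are a
#' simple random sample, so their risk and age distribution mirrors the
#' eligible population. A sub-unity `uptake_ses_differential` lowers
#' inclusion odds in the most deprived fifth, renormalised to preserve the
#' total participant count.
#'
#' @param eligible `data.table` of eligible persons.
#' @param policy a [screening_policy()].
#' @param coverage diffusion coverage fraction for this draw.
#' @param coeffs risk-score coefficients for band assignment.
#' @param seed optional integer seed.
#' @param id_uniforms optional per-person uniforms indexed by `id` (the
#'   engine's common-random-number path for match-eligible selection, which
#'   makes concentrated-screening participants an exact subset of universal
#'   ones).
#' @return `data.table` of participants with `risk`, `risk_band` and
#'   `over60` columns appended.
#' @export
select_participants <- function(eligible, policy, coverage,
                                coeffs = default_risk_coefficients(),
                                seed = NULL, id_uniforms = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  eligible <- as.data.table(eligible)
  n_elig <- nrow(eligible)
  out_cols <- function(dt, risk) {
    dt[, risk := risk]
    dt[, risk_band := risk_band(risk)]
    dt[, over60 := age > 60]
    dt
  }
  if (n_elig == 0 || policy$uptake * coverage <= 0) {
    e <- copy(eligible)
    return(out_cols(e, numeric(0))[0])
  }
  risk <- ten_year_risk(eligible, coeffs)
  w_ses <- ifelse(eligible$imd_fifth == 5, policy$uptake_ses_differential, 1)
  if (identical(policy$participant_risk_mix, "match-eligible")) {
    if (!is.null(id_uniforms)) {
      p <- policy$uptake * coverage * w_ses
      if (policy$uptake_ses_differential != 1) p <- p / mean(w_ses)
      keep <- id_uniforms[eligible$id] < p
      part <- eligible[keep]
      risk <- risk[keep]
    } else {
      n_target <- round(policy$uptake * coverage * n_elig)
      idx <- sample.int(n_elig, min(n_target, n_elig), prob = w_ses)
      part <- eligible[idx]
      risk <- risk[idx]
    }
    return(out_cols(copy(part), risk))
  }
  # explicit mix: IPF-stratified sampling over risk band x over-60
  n_target <- round(policy$uptake * coverage * n_elig)
  band <- risk_band(risk)
  over60 <- eligible$age > 60
  joint <- table(band, over60)
  joint <- matrix(as.numeric(joint), nrow = 3,
                  dimnames = list(c("low", "mid", "high"), c("FALSE", "TRUE")))
  mix <- policy$participant_risk_mix[c("low", "mid", "high")]
  s60 <- policy$share_over_60
  if (identical(s60, "match-eligible")) s60 <- mean(over60)
  row_t <- mix * n_target
  col_t <- c(1 - s60, s60) * n_target
  w <- ipf_cell_targets(joint, row_t, col_t)
  if (any(w > joint + 0.5)) {
    warning("participant mix targets infeasible for the eligible pool; ",
            "using closest feasible mix", call. = FALSE)
    w <- pmin(w, joint)
  }
  # largest-remainder rounding preserving the total within cell capacity
  targets <- pmin(floor(w), joint)
  short <- min(n_target, sum(joint)) - sum(targets)
  if (short > 0) {
    frac <- w - floor(w)
    cap <- joint - targets
    for (k in order(-frac)) {
      if (short <= 0) break
      add <- min(1, cap[k], short)
      targets[k] <- targets[k] + add
      short <- short - add
    }
    cap <- joint - targets
    for (k in order(-cap)) {
      if (short <= 0) break
      add <- min(cap[k], short)
      targets[k] <- targets[k] + add
      short <- short - add
    }
  }
  pick <- integer(0)
  for (b in rownames(joint)) for (o in colnames(joint)) {
    t_bc <- targets[b, o]
    if (t_bc <= 0) next
    cell_idx <- which(band == b & (over60 == (o == "TRUE")))
    pick <- c(pick, if (length(cell_idx) <= t_bc) cell_idx else
      cell_idx[sample.int(length(cell_idx), t_bc, prob = w_ses[cell_idx])])
  }
  out_cols(copy(eligible[pick]), risk[pick])
}

#' Assign treatments to high-risk participants
#'
#' Participants at or above the treatment threshold receive a treatment
#' plan: statins offered with band-specific probability when total
#' cholesterol is at or above 5 mmol/L (24% in the >=20% risk band, 17% in
#' the 10-20% band), antihypertensives with band-specific probability when
#' systolic pressure is at or above 135 mm Hg (27% and 20%), bariatric
#' surgery when BMI exceeds 50, lifestyle counselling always, and a
#' cessation attempt with probability 10% for current smokers.
#'
#' @param participants `data.table` of participants with a `risk` column.
#' @param policy a [screening_policy()].
#' @param seed optional integer seed.
#' @return `data.table` keyed by `id` with logical columns `statin`,
#'   `antihtn`, `bariatric`, `lifestyle`, `cessation_attempt`; participants
#'   below the treatment threshold are omitted (empty plan).
#' @export
assign_treatments <- function(participants, policy, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- as.data.table(participants)[risk >= policy$treatment_threshold]
  n <- nrow(p)
  if (n == 0) {
    return(data.table(id = integer(0), statin = logical(0),
                      antihtn = logical(0), bariatric = logical(0),
                      lifestyle = logical(0), cessation_attempt = logical(0)))
  }
  high <- p$risk >= 0.20
  p_statin <- ifelse(high, policy$statin_uptake[["high"]],
                     policy$statin_uptake[["mid"]])
  p_anti <- ifelse(high, policy$antihtn_uptake[["high"]],
                   policy$antihtn_uptake[["mid"]])
  data.table(
    id = p$id,
    statin = runif(n) < p_statin & p$tchol >= policy$tchol_threshold,
    antihtn = runif(n) < p_anti & p$sbp >= policy$sbp_threshold,
    bariatric = p$bmi > policy$bariatric_bmi_threshold,
    lifestyle = rep(TRUE, n),
    cessation_attempt = runif(n) < policy$cessation_rate &
      p$smoking == "current"
  )
}

#' Apply treatment-plan effects to the population
#'
#' One-time effects are applied immediately: bariatric surgery sets BMI to
#' the target; lifestyle counselling multiplies BMI by 0.99 and, with
#' probability 0.5 each, adds a daily fruit/vegetable portion (if below 5)
#' and an active day (if below 5); cessation attempts move current smokers
#' to former (subject to later relapse). Drug treatments set persistent
#' state: a one-off persistence draw (80% continue beyond the first year)
#' and statin/antihypertensive flags whose exposure effects - scaled by 70%
#' adherence - are overlaid on the lagged exposure stream while treatment is
#' active (see [treatment_overlay()]); a discontinued person's exposures
#' revert to their counterfactual trend values.
#'
#' @param pop population `data.table` (modified in place when
#'   `in_place = TRUE`).
#' @param plan treatment plan from [assign_treatments()].
#' @param policy a [screening_policy()].
#' @param year calendar year of treatment start.
#' @param seed optional integer seed.
#' @param in_place modify by reference.
#' @return the population with treatment state and one-time effects applied.
#' @export
apply_treatment_effects <- function(pop, plan, policy, year, seed = NULL,
                                    in_place = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!in_place) pop <- copy(pop)
  if (nrow(plan) == 0) return(pop)
  idx <- match(plan$id, pop$id)
  stopifnot(!anyNA(idx))
  set(pop, idx, "high_risk", TRUE)
  set(pop, idx, "tx_year", as.integer(year))
  set(pop, idx, "persist_ok", runif(nrow(plan)) < policy$persistence)
  set(pop, idx, "on_statin", plan$statin)
  set(pop, idx, "on_antihtn", plan$antihtn)
  bar <- idx[plan$bariatric & pop$bmi[idx] > policy$bariatric_bmi_threshold]
  if (length(bar)) set(pop, bar, "bmi", policy$bariatric_bmi_target)
  ls <- policy$lifestyle
  li <- idx[plan$lifestyle]
  if (length(li)) {
    set(pop, li, "bmi", pop$bmi[li] * ls$bmi_mult)
    fv <- li[pop$fv_portions[li] < ls$fv_threshold &
               runif(length(li)) < ls$fv_prob]
    if (length(fv)) set(pop, fv, "fv_portions", pop$fv_portions[fv] + 1)
    pa <- li[pop$pa_days[li] < ls$pa_threshold &
               runif(length(li)) < ls$pa_prob]
    if (length(pa)) set(pop, pa, "pa_days", pop$pa_days[pa] + 1L)
  }
  ces <- plan$id[plan$cessation_attempt]
  if (length(ces)) pop <- apply_cessation(pop, ces, in_place = TRUE)
  pop
}

#' Drug-treatment exposure overlay
#'
#' Effective (treated) systolic blood pressure and total cholesterol for a
#' given exposure year: while a person persists with treatment (always in
#' the first year; with the one-off 80% persistence draw thereafter) the
#' drug effect scaled by adherence is subtracted from the stored natural
#' trajectory. Discontinued persons revert to their counterfactual values.
#' An additional population-wide shift (salt-reformulation effect) can be
#' subtracted from everyone's blood pressure.
#'
#' @param pop population `data.table`.
#' @param policy a [screening_policy()] or `NULL`.
#' @param exposure_year the year whose exposures are being evaluated.
#' @param popwide_sbp_shift additional mm Hg subtracted from all systolic
#'   pressures (already scaled by diffusion coverage).
#' @return list with numeric vectors `sbp` and `tchol`.
#' @export
treatment_overlay <- function(pop, policy, exposure_year,
                              popwide_sbp_shift = 0) {
  sbp <- pop$sbp
  tchol <- pop$tchol
  if (!is.null(policy)) {
    active <- !is.na(pop$tx_year) & pop$tx_year <= exposure_year &
      (exposure_year == pop$tx_year | (!is.na(pop$persist_ok) & pop$persist_ok))
    tchol <- tchol - policy$adherence * policy$statin_tchol_reduction *
      (pop$on_statin & active)
    sbp <- sbp - policy$adherence * policy$antihtn_sbp_reduction *
      (pop$on_antihtn & active)
  }
  sbp <- sbp - popwide_sbp_shift
  list(sbp = sbp, tchol = tchol)
}

#' Smoking cessation
#'
#' Moves current smokers to former-smoker status with zero years since
#' quitting and marks them as policy quitters subject to relapse with the
#' general-population relapse schedule (see [relapse_probability()]).
#' Non-smokers are unchanged.
#'
#' @param pop population `data.table`.
#' @param ids person ids attempting cessation.
#' @param in_place modify by reference.
#' @return the population.
#' @export
apply_cessation <- function(pop, ids, in_place = FALSE) {
  if (!in_place) pop <- copy(pop)
  idx <- match(ids, pop$id)
  idx <- idx[!is.na(idx)]
  idx <- idx[pop$smoking[idx] == "current"]
  if (length(idx)) {
    set(pop, idx, "smoking", "former")
    set(pop, idx, "years_since_quit", 0)
    set(pop, idx, "cess_quit", TRUE)
  }
  pop
}

#' Relapse probability for recent quitters
#'
#' Annual probability that a former smoker relapses, by years since
#' quitting. The default schedule declines with time since quitting (0.30,
#' 0.20, 0.10, then 0.05/year) and is shared across sex and deprivation
#' cells; pass a `function(sex, imd_fifth, years_since_quit)` to override
#' with cell-specific rates.
#'
#' @param years_since_quit years since quitting (vectorised).
#' @param sex,imd_fifth passed to a functional `schedule`.
#' @param schedule numeric schedule (indexed from the quit year) with the
#'   last element used beyond its length, or a function.
#' @return relapse probabilities.
#' @export
relapse_probability <- function(years_since_quit, sex = NULL,
                                imd_fifth = NULL,
                                schedule = c(0.30, 0.20, 0.10, 0.05)) {
  if (is.function(schedule)) {
    return(schedule(sex, imd_fifth, years_since_quit))
  }
  i <- pmin(pmax(floor(years_since_quit), 1), length(schedule))
  out <- schedule[i]
  out[is.na(out)] <- 0
  out
}

#' Apply the population-wide policy's stochastic components for one year
#'
#' Fruit-and-vegetable responders are flagged once (never more than the
#' policy's responder share, phased with coverage) and gain one daily
#' portion; during the diffusion period current smokers quit with the
#' per-year hazard `1 - (1 - reduction)^(1/years)` that delivers the
#' targeted relative prevalence reduction by the end of diffusion (these
#' structural quits do not relapse). The blood-pressure shift and BMI-trend
#' damping are deterministic and applied by the engine during exposure
#' advancement.
#'
#' @param pop population `data.table` (modified in place when
#'   `in_place = TRUE`).
#' @param policy a [population_policy()].
#' @param cov_now,cov_prev diffusion coverage in this and the previous year.
#' @param seed optional integer seed.
#' @param id_uniforms optional matrix of per-person uniforms with columns
#'   `fv` and `pq` indexed by `id` (common-random-number path).
#' @param in_place modify by reference.
#' @return the population.
#' @export
apply_population_policy <- function(pop, policy, cov_now, cov_prev,
                                    seed = NULL, id_uniforms = NULL,
                                    in_place = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!in_place) pop <- copy(pop)
  if (cov_now <= 0) return(pop)
  share <- policy$fv_increase_share
  target_new <- share * (cov_now - cov_prev)
  if (target_new > 0) {
    p_flag <- target_new / max(1 - share * cov_prev, 1e-12)
    cand <- which(pop$alive & !pop$fv_resp)
    if (length(cand)) {
      u <- if (!is.null(id_uniforms)) id_uniforms[pop$id[cand], "fv"] else
        runif(length(cand))
      hit <- cand[u < p_flag]
      if (length(hit)) {
        set(pop, hit, "fv_resp", TRUE)
        set(pop, hit, "fv_portions", pop$fv_portions[hit] + 1)
      }
    }
  }
  if (policy$smoking_prev_reduction > 0 && cov_now > cov_prev) {
    h <- 1 - (1 - policy$smoking_prev_reduction)^(1 / policy$reduction_years)
    cand <- which(pop$alive & pop$smoking == "current")
    if (length(cand)) {
      u <- if (!is.null(id_uniforms)) id_uniforms[pop$id[cand], "pq"] else
        runif(length(cand))
      hit <- cand[u < h]
      if (length(hit)) {
        set(pop, hit, "smoking", "former")
        set(pop, hit, "years_since_quit", 0)
      }
    }
  }
  pop
}
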