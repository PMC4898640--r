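test_that("diffusion coverage follows the linear first-year convention", {
  expect_equal(coverage(2010), 0)
  expect_equal(coverage(2011), 0.2)
  expect_equal(coverage(2013), 0.6)
  expect_equal(coverage(2015), 1)
  expect_equal(coverage(2025), 1)
})

test_that("screening eligibility enforces age, disease and area criteria", {
  pol <- screening_policy()
  pop <- ref_pop(5, age = c(39L, 50L, 50L, 50L, 75L))
  pop$diabetes[3] <- 1L
  pop$chd[4] <- TRUE
  elig <- screening_eligibility(pop, pol)
  expect_equal(elig, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  pol45 <- screening_policy(target_fifths = 4:5)
  expect_false(any(screening_eligibility(pop, pol45)))  # all in fifth 3
})

test_that("zero uptake selects nobody and uptake scales the count", {
  pop <- build_population(default_population_spec(), 20000, seed = 42)
  pol <- screening_policy()
  el <- pop[screening_eligibility(pop, pol)]
  none <- select_participants(el, screening_policy(uptake = 0), 1, seed = 1)
  expect_equal(nrow(none), 0)
  part <- select_participants(el, pol, coverage = 1, seed = 2)
  expect_equal(nrow(part), round(0.5 * nrow(el)))
})

test_that("the calibrated participant mix matches its targets", {
  pop <- build_population(default_population_spec(), 20000, seed = 42)
  pol <- screening_policy()
  el <- pop[screening_eligibility(pop, pol)]
  part <- select_participants(el, pol, coverage = 1, seed = 7)
  shares <- prop.table(table(part$risk_band))
  expect_lt(abs(shares[["low"]] - 0.70), 0.02)
  expect_lt(abs(shares[["mid"]] - 0.25), 0.02)
  expect_lt(abs(shares[["high"]] - 0.05), 0.02)
  expect_lt(abs(mean(part$over60) - 0.30), 0.02)
})

test_that("match-eligible selection mirrors the eligible pool", {
  pop <- build_population(default_population_spec(), 20000, seed = 42)
  pol <- screening_policy(participant_risk_mix = "match-eligible",
                          share_over_60 = "match-eligible")
  el <- pop[screening_eligibility(pop, pol)]
  part <- select_participants(el, pol, coverage = 1, seed = 3)
  pool_risk <- ten_year_risk(el)
  expect_lt(abs(mean(part$risk) - mean(pool_risk)), 0.01)
  expect_lt(abs(mean(part$over60) - mean(el$age > 60)), 0.02)
})

test_that("a deprivation uptake differential lowers fifth-5 participation", {
  pop <- build_population(default_population_spec(), 20000, seed = 42)
  pol <- screening_policy(participant_risk_mix = "match-eligible",
                          share_over_60 = "match-eligible",
                          uptake_ses_differential = 0.5)
  el <- pop[screening_eligibility(pop, pol)]
  u <- local({ set.seed(17); runif(max(el$id)) })
  part <- select_participants(el, pol, coverage = 1, id_uniforms = u)
  f5_pool <- mean(el$imd_fifth == 5)
  f5_part <- mean(part$imd_fifth == 5)
  expect_lt(f5_part, 0.8 * f5_pool)
})

test_that("concentrated participants are the universal ones in fifths 4-5", {
  pop <- build_population(default_population_spec(), 20000, seed = 42)
  uni <- screening_policy(participant_risk_mix = "match-eligible",
                          share_over_60 = "match-eligible")
  con <- screening_policy(target_fifths = 4:5,
                          participant_risk_mix = "match-eligible",
                          share_over_60 = "match-eligible")
  u <- local({ set.seed(23); runif(max(pop$id)) })
  pu <- select_participants(pop[screening_eligibility(pop, uni)], uni, 0.2,
                            id_uniforms = u)
  pc <- select_participants(pop[screening_eligibility(pop, con)], con, 0.2,
                            id_uniforms = u)
  expect_setequal(pc$id, pu$id[pu$imd_fifth %in% 4:5])
})

test_that("treatment assignment follows band- and threshold-specific rules", {
  pol <- screening_policy()
  low <- data.table(id = 1L, risk = 0.05, tchol = 6, sbp = 150, bmi = 30,
                    smoking = "never")
  expect_equal(nrow(assign_treatments(low, pol, seed = 1)), 0)
  n <- 20000
  high <- data.table(id = seq_len(n), risk = 0.25, tchol = 5.6, sbp = 140,
                     bmi = 30, smoking = "never")
  plan <- assign_treatments(high, pol, seed = 2)
  expect_lt(abs(mean(plan$statin) - 0.24), 3 * sqrt(0.24 * 0.76 / n))
  expect_lt(abs(mean(plan$antihtn) - 0.27), 3 * sqrt(0.27 * 0.73 / n))
  mid <- data.table(id = seq_len(n), risk = 0.15, tchol = 5.6, sbp = 140,
                    bmi = 30, smoking = "never")
  plan_mid <- assign_treatments(mid, pol, seed = 3)
  expect_lt(abs(mean(plan_mid$statin) - 0.17), 3 * sqrt(0.17 * 0.83 / n))
  expect_lt(abs(mean(plan_mid$antihtn) - 0.20), 3 * sqrt(0.20 * 0.80 / n))
  low_chol <- data.table(id = seq_len(100), risk = 0.25, tchol = 4.0,
                         sbp = 120, bmi = 30, smoking = "never")
  plan_lc <- assign_treatments(low_chol, pol, seed = 4)
  expect_false(any(plan_lc$statin))
  expect_false(any(plan_lc$antihtn))
  expect_true(all(plan_lc$lifestyle))
})

test_that("one-time treatment effects are applied as specified", {
  pol <- screening_policy()
  pop <- ref_pop(3, bmi = c(52, 28, 28), fv_portions = c(5, 3, 5))
  plan <- data.table(id = 1:3, statin = FALSE, antihtn = FALSE,
                     bariatric = c(TRUE, FALSE, FALSE), lifestyle = TRUE,
                     cessation_attempt = FALSE)
  pol1 <- screening_policy(lifestyle = list(fv_threshold = 5, fv_prob = 1,
                                            pa_threshold = 5, pa_prob = 1,
                                            bmi_mult = 0.99))
  out <- apply_treatment_effects(pop, plan, pol1, 2011, seed = 5)
  expect_equal(out$bmi[1], 30 * 0.99)  # surgery then 1% lifestyle reduction
  expect_equal(out$bmi[2], 28 * 0.99)
  expect_equal(out$fv_portions[2], 4)  # below 5: gains a portion
  expect_equal(out$fv_portions[3], 5)  # at threshold: unchanged
})

test_that("drug overlays scale by adherence and honour persistence", {
  pol <- screening_policy()
  pop <- ref_pop(2, sbp = 150, tchol = 6)
  pop$on_statin <- TRUE; pop$on_antihtn <- TRUE
  pop$tx_year <- 2012L
  pop$persist_ok <- c(TRUE, FALSE)
  # before treatment starts: natural values
  eff <- treatment_overlay(pop, pol, 2011)
  expect_equal(eff$sbp, c(150, 150))
  # first treatment year: everyone treated
  eff <- treatment_overlay(pop, pol, 2012)
  expect_equal(eff$sbp, c(150, 150) - 0.7 * 10)
  expect_equal(eff$tchol, c(6, 6) - 0.7 * 1.3)
  # later years: only persisters keep the effect; discontinuers revert
  eff <- treatment_overlay(pop, pol, 2014)
  expect_equal(eff$sbp, c(150 - 7, 150))
  expect_equal(eff$tchol, c(6 - 0.91, 6))
})

test_that("treatment never moves exposures toward higher risk", {
  set.seed(61)
  pol <- screening_policy()
  pop <- build_population(default_population_spec(), 2000, seed = 62)
  part <- copy(pop)[age >= 40 & age <= 74][1:500]
  part[, risk := pmax(ten_year_risk(part), 0.12)]
  plan <- assign_treatments(part, pol)
  before <- copy(pop)
  out <- apply_treatment_effects(pop, plan, pol, 2011)
  idx <- match(out$id, before$id)
  expect_true(all(out$bmi <= before$bmi[idx] + 1e-12))
  expect_true(all(out$fv_portions >= before$fv_portions[idx]))
  expect_true(all(out$pa_days >= before$pa_days[idx]))
  eff <- treatment_overlay(out, pol, 2011)
  expect_true(all(eff$sbp <= out$sbp + 1e-12))
  expect_true(all(eff$tchol <= out$tchol + 1e-12))
})

test_that("cessation converts smokers and relapse restores them", {
  pop <- ref_pop(3, smoking = c("never", "current", "current"))
  out <- apply_cessation(pop, ids = 1:3)
  expect_equal(out$smoking, c("never", "former", "former"))
  expect_equal(out$years_since_quit[2:3], c(0, 0))
  expect_true(all(out$cess_quit[2:3]))
  # relapse schedule lookups
  expect_equal(relapse_probability(0), 0.30)
  expect_equal(relapse_probability(2), 0.20)
  expect_equal(relapse_probability(10), 0.05)
  flat <- relapse_probability(c(0, 3, 9), schedule = 0.3)
  expect_equal(flat, rep(0.3, 3))
  # one-year survival of quitting under a flat 0.3 schedule
  set.seed(71)
  n <- 1e4
  still <- mean(runif(n) >= relapse_probability(rep(1, n), schedule = 0.3))
  expect_lt(abs(still - 0.7), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("the population policy is inert at zero coverage", {
  pol <- population_policy()
  pop <- build_population(default_population_spec(), 1000, seed = 81)
  out <- apply_population_policy(copy(pop), pol, cov_now = 0, cov_prev = 0,
                                 seed = 1)
  expect_equal(as.data.frame(out), as.data.frame(pop))
})

test_that("fruit-and-vegetable responders reach half the population", {
  pol <- population_policy()
  pop <- build_population(default_population_spec(), 20000, seed = 82)
  fv0 <- copy(pop$fv_portions)
  covs <- coverage(2011:2015)
  prev <- 0
  set.seed(83)
  for (i in seq_along(covs)) {
    apply_population_policy(pop, pol, covs[i], prev, in_place = TRUE)
    prev <- covs[i]
  }
  share <- mean(pop$fv_resp)
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / nrow(pop)))
  expect_equal(pop$fv_portions[pop$fv_resp], fv0[pop$fv_resp] + 1)
})

test_that("structural quitting delivers the five-year prevalence target", {
  pol <- population_policy()
  spec <- single_stratum_spec(overrides = zero_slope_overrides())
  pop <- build_population(spec, 20000, seed = 84)
  prev0 <- mean(pop$smoking == "current")
  covs <- coverage(2011:2015)
  prev <- 0
  set.seed(85)
  for (i in seq_along(covs)) {
    apply_population_policy(pop, pol, covs[i], prev, in_place = TRUE)
    prev <- covs[i]
  }
  prev5 <- mean(pop$smoking == "current")
  target <- prev0 * (1 - 0.13)
  se <- sqrt(target * (1 - target) / nrow(pop))
  expect_lt(abs(prev5 - target), 3 * se)
})

test_that("sensitivity variants carry their documented parameter changes", {
  sv <- sensitivity_scenarios()
  expect_equal(sv$universal_threshold20$screening$treatment_threshold, 0.20)
  expect_equal(
    sv$universal_uptake_differential$screening$uptake_ses_differential, 0.9)
  expect_equal(
    sv$population_wide_diet_only$population_policy$smoking_prev_reduction, 0)
})
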