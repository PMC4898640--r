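rr_tab <- default_relative_risks()

test_that("combined relative risk is 1 at the reference profile", {
  p <- ref_profile()
  expect_equal(combined_rr(p, rr_tab, "chd"), 1)
  expect_equal(combined_rr(p, rr_tab, "stroke"), 1)
})

test_that("categorical exposures multiply their tabulated relative risks", {
  p <- ref_profile(smoking = "current", diabetes = 1L)
  rr_smk <- rr_tab[exposure == "smoking" & disease == "chd" &
                     level == "current", rr]
  rr_dm <- rr_tab[exposure == "diabetes" & disease == "chd", rr]
  expect_equal(combined_rr(p, rr_tab, "chd"), rr_smk * rr_dm,
               tolerance = 1e-12)
})

test_that("continuous exposures exponentiate per unit above reference", {
  tab <- copy(rr_tab)
  tab[exposure == "sbp" & disease == "chd",
      `:=`(rr = 1.25, per = 10, ref = 115, ci_lo = 1.15, ci_hi = 1.35)]
  p <- ref_profile(sbp = 135)
  expect_equal(combined_rr(p, tab, "chd"), 1.25^2, tolerance = 1e-12)
})

test_that("protective contributions are floored per factor", {
  tab <- copy(rr_tab)
  tab[exposure == "tchol" & disease == "chd",
      `:=`(rr = 3.0, ci_lo = 2.5, ci_hi = 3.5)]
  p <- ref_profile(tchol = 2.0)  # 1.8 mmol/L below reference: 3^-1.8 < 0.5
  expect_equal(combined_rr(p, tab, "chd"), 0.5, tolerance = 1e-12)
})

test_that("an exposure absent from the risk table is a configuration error", {
  tab <- rr_tab[exposure != "bmi"]
  expect_error(combined_rr(ref_profile(), tab, "chd"), "bmi")
})

test_that("baseline probability calibration solves mean(p0 * rr) = target", {
  expect_equal(calibrate_baseline_probability(0.02, c(1, 1, 1)), 0.02)
  expect_equal(calibrate_baseline_probability(0.02, c(1, 3)), 0.01)
  expect_error(calibrate_baseline_probability(0.02, numeric(0)))
  # a heavy-tailed risk distribution forces the cap: p0 * max(rr) = 1
  rr_skew <- c(rep(0.5, 99), 100)
  expect_warning(p0 <- calibrate_baseline_probability(0.1, rr_skew),
                 "capped")
  expect_equal(p0 * max(rr_skew), 1)
  # closure property over randomised risk distributions
  set.seed(20)
  for (i in 1:50) {
    rr <- exp(rnorm(200, 0, 0.7))
    target <- runif(1, 0.001, 0.05)
    p0 <- calibrate_baseline_probability(target, rr)
    expect_equal(mean(p0 * rr), target, tolerance = 1e-12)
  }
})

test_that("population-level calibration reproduces configured rates", {
  rates <- default_baseline_rates()
  pop <- build_population(default_population_spec(), 20000, seed = 8)
  p0 <- cvdmicrosim:::calibrate_p0(pop, rates, rr_table = rr_tab)
  rr_chd <- combined_rr(pop, rr_tab, "chd")
  dt <- data.table(ageband = age_band(pop$age), sex = pop$sex, rr = rr_chd)
  chk <- merge(dt[, .(mean_rr = mean(rr)), by = .(ageband, sex)],
               p0[p0$disease == "chd"], by = c("ageband", "sex"))
  chk <- merge(chk, rates$incidence[rates$incidence$disease == "chd"],
               by = c("ageband", "sex"))
  expect_equal(chk$prob0 * chk$mean_rr, chk$rate, tolerance = 1e-12)
})

test_that("a prior first-ever event zeroes that disease's incidence", {
  rates <- default_baseline_rates()
  pop <- ref_pop(4)
  pop$chd[1:2] <- TRUE
  pr <- annual_event_probabilities(pop, rates, rr_tab, 2011)
  expect_equal(pr$chd_inc[1:2], c(0, 0))
  expect_gt(pr$chd_inc[3], 0)
  expect_true(all(pr$stroke_inc > 0))
})

test_that("reference persons receive exactly the calibrated baseline", {
  rates <- default_baseline_rates()
  pop <- ref_pop(10, age = 62, sex = "male")
  pr <- annual_event_probabilities(pop, rates, rr_tab, 2011)
  target <- rates$incidence[disease == "chd" & ageband == "60-64" &
                              sex == "male", rate]
  # all-reference population: mean rr = 1, so p0 equals the target rate
  expect_equal(pr$chd_inc, rep(target, 10), tolerance = 1e-12)
})

test_that("incidence is linear in the relative risk before capping", {
  rates <- default_baseline_rates()
  pop <- ref_pop(1, smoking = "current")
  for (k in 1:5) pop[[paste0("smk_l", k)]] <- "current"
  p0 <- data.table(disease = c("chd", "stroke"), ageband = "55-59",
                   sex = "male", prob0 = 0.005)
  tab2 <- copy(rr_tab)
  tab2[exposure == "smoking" & level == "current",
       `:=`(rr = rr * 2, ci_hi = ci_hi * 3)]
  pr1 <- annual_event_probabilities(pop, rates, rr_tab, 2011, p0 = p0)
  pr2 <- annual_event_probabilities(pop, rates, tab2, 2011, p0 = p0)
  expect_equal(pr2$chd_inc, 2 * pr1$chd_inc, tolerance = 1e-12)
})

test_that("case fatality decays geometrically and grades with deprivation", {
  rates <- default_baseline_rates()
  cf0 <- case_fatality(62, "male", 3, "chd", 2011, rates)
  expect_equal(cf0, rates$case_fatality[disease == "chd" &
                                          ageband == "60-64" &
                                          sex == "male", cf])
  expect_equal(case_fatality(62, "male", 3, "chd", 2012, rates), 0.97 * cf0)
  expect_equal(case_fatality(62, "male", 3, "chd", 2021, rates),
               cf0 * 0.97^10, tolerance = 1e-12)
  expect_equal(case_fatality(62, "male", 5, "chd", 2011, rates),
               cf0 * 1.05^2, tolerance = 1e-12)
  expect_gt(case_fatality(62, "male", 5, "chd", 2011, rates),
            case_fatality(62, "male", 1, "chd", 2011, rates))
})

test_that("the ten-year risk score follows its Cox form and monotonicities", {
  co <- default_risk_coefficients()
  ref <- ref_pop(1, age = co$ref$age, sex = "male", imd = co$ref$imd,
                 sbp = co$ref$sbp, tchol = co$ref$tchol, bmi = co$ref$bmi)
  expect_equal(ten_year_risk(ref, co), 1 - co$S0[["male"]],
               tolerance = 1e-12)
  co1 <- co; co1$S0 <- c(male = 1, female = 1)
  risky <- ref_pop(1, age = 80, smoking = "current", sbp = 180)
  expect_equal(ten_year_risk(risky, co1), 0)
  ages <- seq(40, 74, 2)
  r <- ten_year_risk(ref_pop(length(ages), age = ages), co)
  expect_true(all(diff(r) > 0))
  expect_gt(ten_year_risk(ref_pop(1, age = 64), co),
            ten_year_risk(ref_pop(1, age = 40), co))
  expect_gt(ten_year_risk(ref_pop(1, smoking = "current"), co),
            ten_year_risk(ref_pop(1), co))
  expect_gt(ten_year_risk(ref_pop(1, imd = 5), co),
            ten_year_risk(ref_pop(1, imd = 1), co))
})

test_that("incidence responds to exposures five years back, not current", {
  rates <- default_baseline_rates()
  base <- ref_pop(1)
  p0 <- cvdmicrosim:::calibrate_p0(base, rates, rr_table = rr_tab)
  cur <- copy(base); cur$sbp <- 170   # current-year change only
  lag <- copy(base); lag$sbp_l5 <- 170
  pr_b <- annual_event_probabilities(base, rates, rr_tab, 2011, p0 = p0)
  pr_c <- annual_event_probabilities(cur, rates, rr_tab, 2011, p0 = p0)
  pr_l <- annual_event_probabilities(lag, rates, rr_tab, 2011, p0 = p0)
  expect_equal(pr_c$chd_inc, pr_b$chd_inc, tolerance = 1e-12)
  expect_gt(pr_l$chd_inc, pr_b$chd_inc)
})

test_that("all emitted probabilities stay within [0, 1]", {
  rates <- default_baseline_rates()
  set.seed(30)
  for (i in 1:20) {
    tab <- copy(rr_tab)
    tab[, rr := rr * exp(rnorm(.N, 0, 0.5))]
    tab[, `:=`(ci_lo = pmin(ci_lo, rr), ci_hi = pmax(ci_hi, rr))]
    pop <- build_population(default_population_spec(), 300,
                            seed = 1000 + i)
    pr <- suppressWarnings(
      annual_event_probabilities(pop, rates, tab, 2011 + (i %% 20)))
    probs <- as.matrix(pr[, .(chd_inc, stroke_inc, chd_death, stroke_death,
                              other_death)])
    expect_true(all(probs >= 0 & probs <= 1))
  }
})
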