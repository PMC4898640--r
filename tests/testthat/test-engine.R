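test_that("competing event draws honour degenerate probabilities", {
  probs <- data.table(chd_inc = 0, stroke_inc = 0, chd_death = 0,
                      stroke_death = 0, other_death = 0)
  out <- competing_event_draw(probs, seed = 1)
  expect_false(out$chd_inc); expect_false(out$stroke_inc)
  expect_true(is.na(out$death))
  probs$other_death <- 1
  out <- competing_event_draw(probs, seed = 1)
  expect_identical(out$death, "other")
})

test_that("event frequencies match their probabilities", {
  n <- 1e5
  probs <- data.table(chd_inc = rep(0.02, n), stroke_inc = 0, chd_death = 0,
                      stroke_death = 0, other_death = 0)
  out <- competing_event_draw(probs, seed = 99)
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(mean(out$chd_inc) - 0.02), 3 * se)
})

test_that("cause probabilities summing above one are renormalised", {
  probs <- data.table(chd_inc = 0, stroke_inc = 0, chd_death = 0.7,
                      stroke_death = 0.7, other_death = 0.2)
  expect_warning(out <- competing_event_draw(probs, seed = 5),
                 "renormalised")
  expect_false(is.na(out$death))  # total probability 1 after renormalisation
})

test_that("an empty population steps without error", {
  spec <- default_population_spec()
  pop <- build_population(spec, 10, seed = 1)[0]
  ctx <- cvdmicrosim:::make_ctx(spec, default_baseline_rates(),
                                default_relative_risks(),
                                default_risk_coefficients(),
                                scenario_baseline(), 1L, 2011:2030, 10,
                                c(0.3, 0.2, 0.1, 0.05))
  recs <- step_year(pop, ctx, 2011)
  expect_equal(nrow(recs), 0)
})

test_that("identical seeds and configs give identical result cubes", {
  a <- run_iteration(scenario_baseline(), iter_seed = 21, n = 1500,
                     years = 2011:2016)
  b <- run_iteration(scenario_baseline(), iter_seed = 21, n = 1500,
                     years = 2011:2016)
  expect_cube_equal(a, b)
})

test_that("persons are conserved through deaths, exits and entries", {
  # a young single-band population cannot age out over a short horizon
  spec <- single_stratum_spec("30-34", "male", 3)
  pop <- build_population(spec, 1000, seed = 4)
  ctx <- cvdmicrosim:::make_ctx(spec, default_baseline_rates(),
                                default_relative_risks(),
                                default_risk_coefficients(),
                                scenario_baseline(), 4L, 2011:2015, 1000,
                                c(0.3, 0.2, 0.1, 0.05))
  for (y in 2011:2015) {
    n_start <- nrow(pop)
    recs <- step_year(pop, ctx, y)
    pop <- ctx$pop
    deaths <- recs[outcome %in% c("cvd_death", "other_death"), sum(count)]
    expect_equal(nrow(pop), n_start - deaths + ctx$n_entrants)
    expect_equal(recs[outcome == "alive", sum(count)], n_start - deaths)
  }
})

test_that("persons older than 84 leave the simulation", {
  spec <- single_stratum_spec("80-84", "female", 3)
  pop <- build_population(spec, 500, seed = 6)
  ctx <- cvdmicrosim:::make_ctx(spec, default_baseline_rates(),
                                default_relative_risks(),
                                default_risk_coefficients(),
                                scenario_baseline(), 6L, 2011:2015, 500,
                                c(0.3, 0.2, 0.1, 0.05))
  n84 <- sum(pop$age == 84)
  n_start <- nrow(pop)
  recs <- step_year(pop, ctx, 2011)
  pop <- ctx$pop
  deaths <- recs[outcome %in% c("cvd_death", "other_death"), sum(count)]
  expect_true(all(pop$age <= 84))
  # survivors aged 84 exited; entrants for the 80-84 band spec are zero
  expect_equal(ctx$n_entrants, 0)
  expect_lte(nrow(pop), n_start - deaths - n84 +
               recs[outcome %in% c("cvd_death", "other_death") &
                      ageband == "80-84", sum(count)])
})

test_that("each person contributes at most one first-ever event per disease", {
  # inflate incidence so repeat events would be very likely if allowed
  rates <- default_baseline_rates()
  rates$incidence <- copy(rates$incidence)[, rate := pmin(rate * 50, 0.5)]
  cube <- suppressWarnings(
    run_iteration(scenario_baseline(), iter_seed = 31, n = 500, rates = rates,
                  years = 2011:2020))
  max_persons <- 500 + 10 * 20  # initial + a generous entrants bound
  expect_lte(cube[outcome == "chd_case", sum(count)], max_persons)
  expect_lte(cube[outcome == "stroke_case", sum(count)], max_persons)
})

test_that("a single Monte Carlo iteration yields a singleton axis", {
  cube <- run_mc(scenario_baseline(), mc_config(n_iterations = 1,
                                                master_seed = 2),
                 n = 800, years = 2011:2013)
  expect_equal(unique(cube$iteration), 1L)
  expect_equal(unique(cube$scenario), "baseline")
})

test_that("iterations are exchangeable under seed permutation", {
  s <- c(101L, 202L)
  m1 <- mc_config(n_iterations = 2, iteration_seeds = s)
  m2 <- mc_config(n_iterations = 2, iteration_seeds = rev(s))
  c1 <- run_mc(scenario_baseline(), m1, n = 800, years = 2011:2013)
  c2 <- run_mc(scenario_baseline(), m2, n = 800, years = 2011:2013)
  expect_cube_equal(c1[c1$iteration == 1][, iteration := NULL],
                    c2[c2$iteration == 2][, iteration := NULL])
  expect_cube_equal(c1[c1$iteration == 2][, iteration := NULL],
                    c2[c2$iteration == 1][, iteration := NULL])
})

test_that("lowering everyone's blood pressure cannot increase median cases", {
  lower_sbp <- scenario_config(
    "sbp_down",
    population_policy = population_policy(bmi_trend_damping = 0,
                                          sbp_shift = 10,
                                          fv_increase_share = 0,
                                          smoking_prev_reduction = 0))
  mc <- mc_config(n_iterations = 8, master_seed = 14, sample_rr = FALSE)
  cube <- run_mc(list(scenario_baseline(), lower_sbp), mc, n = 4000,
                 years = 2011:2026)
  cases <- cube[outcome %in% c("chd_case", "stroke_case") & year >= 2016,
                .(cases = sum(count)), by = .(scenario, iteration)]
  med <- cases[, .(m = median(cases)), by = scenario]
  expect_lte(med[scenario == "sbp_down", m],
             med[scenario == "baseline", m])
  # under common random numbers the reduction holds iteration by iteration
  wide <- dcast(cases, iteration ~ scenario, value.var = "cases")
  expect_true(all(wide$sbp_down <= wide$baseline))
})
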