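# Discrete-time annual engine: competing-risk event draws, the yearly
# sub-step loop, and second-order Monte Carlo orchestration with common
# random numbers across scenarios.

UNIFORM_COLS <- c("dm", "smk", "ets", "chd", "stroke", "death",
                  "recruit", "fv", "pq")

# Per-(iteration, year) matrix of uniforms indexed by person id. Every
# first-order random event consumes the uniform belonging to its person id,
# so scenarios sharing an iteration seed share random numbers exactly.
year_uniforms <- function(iter_seed, year, max_id) {
  set.seed(substream_seed(iter_seed, "events", year))
  matrix(runif(max_id * length(UNIFORM_COLS)), nrow = max_id,
         dimnames = list(NULL, UNIFORM_COLS))
}

#' Draw competing events for one person-year
#'
#' Incidence of CHD and of stroke are independent Bernoulli draws (both
#' diseases may begin in the same year). Death is a single draw across the
#' mutually exclusive causes, resolved on the cumulative probability scale
#' in the fixed order other-cause, CHD, stroke; if the cause probabilities
#' sum above 1 they are renormalised (with a warning).
#'
#' @param probs `data.table`/list with numeric fields `chd_inc`,
#'   `stroke_inc`, `chd_death`, `stroke_death`, `other_death` (vectorised).
#' @param u optional matrix of uniforms with columns `chd`, `stroke`,
#'   `death` (one row per person); drawn internally when absent.
#' @param seed optional integer seed.
#' @return `data.table` with logical `chd_inc`, `stroke_inc` and character
#'   `death` (`NA`, `"other"`, `"chd"` or `"stroke"`).
#' @export
competing_event_draw <- function(probs, u = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(probs$chd_inc)
  if (is.null(u)) {
    u <- matrix(runif(3 * n), ncol = 3,
                dimnames = list(NULL, c("chd", "stroke", "death")))
  }
  p_cd <- probs$chd_death
  p_sd <- probs$stroke_death
  p_od <- probs$other_death
  tot <- p_cd + p_sd + p_od
  over <- tot > 1
  if (any(over)) {
    warning(sum(over), " person-year(s) with cause-of-death probabilities ",
            "summing above 1; renormalised", call. = FALSE)
    p_cd[over] <- p_cd[over] / tot[over]
    p_sd[over] <- p_sd[over] / tot[over]
    p_od[over] <- p_od[over] / tot[over]
  }
  ud <- u[, "death"]
  death <- rep(NA_character_, n)
  death[ud < p_od + p_cd + p_sd] <- "stroke"
  death[ud < p_od + p_cd] <- "chd"
  death[ud < p_od] <- "other"
  data.table(
    chd_inc = u[, "chd"] < probs$chd_inc,
    stroke_inc = u[, "stroke"] < probs$stroke_inc,
    death = death
  )
}

# Tally person-level events into the stratified results format.
tally_events <- function(pop, flag, outcome) {
  if (!any(flag)) return(NULL)
  pop[flag, .(count = .N), by = .(ageband = age_band(age), sex, imd_fifth)][
    , outcome := outcome][]
}

#' Advance the simulation by one year
#'
#' Runs the fixed within-year sub-steps on an alive population:
#' (1) secular trend advance with the five-year lag-buffer push (treatment
#' and population-policy overlays enter the buffer here); (2) scenario
#' policy actions for the year - screening recruitment, treatment
#' assignment and effects, relapse of policy quitters, population-policy
#' responder flagging and structural quits; (3) event probabilities from
#' the exposures of five years earlier; (4) competing-risk event draws with
#' per-person common random numbers; (5) stratified recording; (6) aging,
#' exit above age 84, and entry of a new 30-year-old cohort.
#'
#' @param pop population `data.table` of alive persons (modified by
#'   reference).
#' @param ctx engine context environment created by [run_iteration()].
#' @param year calendar year to simulate.
#' @return `data.table` of event records for the year (columns `year`,
#'   `ageband`, `sex`, `imd_fifth`, `outcome`, `count`); the advanced
#'   population is `ctx$pop`.
#' @export
step_year <- function(pop, ctx, year) {
  spec <- ctx$spec
  scen <- ctx$scenario
  if (nrow(pop) == 0) {
    ctx$pop <- pop
    return(data.table(year = integer(0), ageband = character(0),
                      sex = character(0), imd_fifth = integer(0),
                      outcome = character(0), count = integer(0)))
  }
  U <- year_uniforms(ctx$iter_seed, year, ctx$max_id)
  scr <- scen$screening
  ppol <- scen$population_policy

  # (1) trend advance + lag push of last year's (effective) exposures
  eyear <- year - 1L
  shift <- if (!is.null(ppol)) {
    ppol$sbp_shift * coverage(eyear, scen$start_year, scen$diffusion_years)
  } else 0
  eff <- treatment_overlay(pop, scr, eyear, popwide_sbp_shift = shift)
  eff$sbp <- clamp(eff$sbp, spec$factors$sbp$bounds)
  eff$tchol <- clamp(eff$tchol, spec$factors$tchol$bounds)
  bmi_mult <- if (!is.null(ppol)) {
    1 - ppol$bmi_trend_damping * coverage(year, scen$start_year,
                                          scen$diffusion_years)
  } else 1
  advance_exposures(pop, spec, year, effective = list(sbp = eff$sbp,
                                                      tchol = eff$tchol),
                    u = U[pop$id, c("dm", "smk", "ets"), drop = FALSE],
                    bmi_slope_mult = bmi_mult, in_place = TRUE)

  # (2) policy actions for this year
  cov_now <- coverage(year, scen$start_year, scen$diffusion_years)
  cov_prev <- coverage(year - 1, scen$start_year, scen$diffusion_years)
  if (!is.null(scr) && cov_now > 0) {
    set.seed(substream_seed(ctx$iter_seed, "policy", year))
    # relapse of earlier policy quitters before this year's recruitment
    rel <- which(pop$cess_quit & pop$smoking == "former")
    if (length(rel)) {
      p_rel <- relapse_probability(pop$years_since_quit[rel], pop$sex[rel],
                                   pop$imd_fifth[rel],
                                   schedule = ctx$relapse_schedule)
      back <- rel[runif(length(rel)) < p_rel]
      if (length(back)) {
        set(pop, back, "smoking", "current")
        set(pop, back, "years_since_quit", NA_real_)
        set(pop, back, "cess_quit", FALSE)
      }
    }
    eligible <- pop[screening_eligibility(pop, scr) & !screened]
    if (nrow(eligible)) {
      # rolling recruitment: each year invites 1/diffusion_years of the
      # never-screened eligible pool, reaching full uptake over diffusion.
      # Closest-feasible-mix warnings are tallied into the run log rather
      # than raised per year.
      part <- withCallingHandlers(
        select_participants(
          eligible, scr, coverage = 1 / scen$diffusion_years,
          coeffs = ctx$coeffs,
          id_uniforms = if (identical(scr$participant_risk_mix,
                                      "match-eligible")) U[, "recruit"]),
        warning = function(w) {
          if (grepl("closest feasible mix", conditionMessage(w))) {
            ctx$mix_warnings <- (ctx$mix_warnings %||% 0L) + 1L
            invokeRestart("muffleWarning")
          }
        })
      if (nrow(part)) {
        set(pop, match(part$id, pop$id), "screened", TRUE)
        plan <- assign_treatments(part, scr)
        apply_treatment_effects(pop, plan, scr, year, in_place = TRUE)
      }
    }
  }
  if (!is.null(ppol) && cov_now > 0) {
    apply_population_policy(pop, ppol, cov_now, cov_prev,
                            id_uniforms = U[, c("fv", "pq"), drop = FALSE],
                            in_place = TRUE)
  }

  # (3) event probabilities from the five-year-lagged exposures
  if (is.null(ctx$p0)) {
    ctx$p0 <- calibrate_p0(pop, ctx$rates, rr_table = ctx$rr_table)
  }
  pr <- annual_event_probabilities(pop, ctx$rates, ctx$rr_table, year,
                                   p0 = ctx$p0)

  # (4) competing-risk draws; disease death requires the disease flag
  un <- U[pop$id, , drop = FALSE]
  chd_new <- !pop$chd & un[, "chd"] < pr$chd_inc
  stroke_new <- !pop$stroke & un[, "stroke"] < pr$stroke_inc
  cf_c <- case_fatality(pop$age, pop$sex, pop$imd_fifth, "chd", year,
                        ctx$rates)
  cf_s <- case_fatality(pop$age, pop$sex, pop$imd_fifth, "stroke", year,
                        ctx$rates)
  p_cd <- fifelse(pop$chd, cf_c * ctx$rates$prevalent_cf_mult,
                  fifelse(chd_new, cf_c, 0))
  p_sd <- fifelse(pop$stroke, cf_s * ctx$rates$prevalent_cf_mult,
                  fifelse(stroke_new, cf_s, 0))
  p_od <- pr$other_death
  tot <- p_od + p_cd + p_sd
  over <- tot > 1
  if (any(over)) {
    ctx$renormalised <- (ctx$renormalised %||% 0L) + sum(over)
    p_cd[over] <- p_cd[over] / tot[over]
    p_sd[over] <- p_sd[over] / tot[over]
    p_od[over] <- p_od[over] / tot[over]
  }
  ud <- un[, "death"]
  death <- rep(NA_character_, nrow(pop))
  death[ud < p_od + p_cd + p_sd] <- "stroke"
  death[ud < p_od + p_cd] <- "chd"
  death[ud < p_od] <- "other"

  # (5) stratified recording
  set(pop, which(chd_new), "chd", TRUE)
  set(pop, which(stroke_new), "stroke", TRUE)
  dead <- !is.na(death)
  recs <- rbindlist(list(
    tally_events(pop, chd_new, "chd_case"),
    tally_events(pop, stroke_new, "stroke_case"),
    tally_events(pop, dead & death %in% c("chd", "stroke"), "cvd_death"),
    tally_events(pop, dead & death == "other", "other_death"),
    tally_events(pop, !dead, "alive")
  ))
  recs[, year := as.integer(year)]
  setcolorder(recs, c("year", "ageband", "sex", "imd_fifth", "outcome",
                      "count"))

  # (6) survivors age one year; exits above 84; new 30-year-olds enter
  pop <- pop[!dead]
  set(pop, NULL, "age", pop$age + 1L)
  pop <- pop[age <= 84L]
  if (ctx$n_entrants > 0) {
    yi <- year - ctx$years[1]
    ent <- new_entrants(spec, ctx$n_entrants, year,
                        seed = substream_seed(ctx$iter_seed, "entrants", year),
                        id_start = ctx$entrant_id_start + yi * ctx$n_entrants)
    pop <- rbind(pop, ent, use.names = TRUE)
  }
  ctx$pop <- pop
  recs
}

# Build the per-iteration engine context.
make_ctx <- function(spec, rates, rr_table, coeffs, scenario, iter_seed,
                     years, n, relapse_schedule) {
  band1_share <- {
    s <- spec$strata
    sum(s$count[s$ageband == age_band_labels()[1]]) / sum(s$count) / 5
  }
  ctx <- new.env(parent = emptyenv())
  ctx$spec <- spec
  ctx$rates <- rates
  ctx$rr_table <- rr_table
  ctx$coeffs <- coeffs
  ctx$scenario <- scenario
  ctx$iter_seed <- iter_seed
  ctx$years <- years
  ctx$p0 <- NULL
  ctx$n_entrants <- round(n * band1_share)
  ctx$entrant_id_start <- n + 1L
  ctx$max_id <- as.integer(n + length(years) * ctx$n_entrants)
  ctx$relapse_schedule <- relapse_schedule
  ctx$renormalised <- 0L
  ctx
}

#' Run one Monte Carlo iteration of one scenario
#'
#' Simulates the annual loop over the full horizon for a single scenario
#' and a single second-order parameter draw. The iteration seed determines
#' the synthetic population, the parameter draw and every per-year
#' first-order random stream; two scenarios run with the same iteration
#' seed share the population and the event uniforms (common random
#' numbers), so scenario differences isolate intervention effects.
#'
#' @param scenario a [scenario_config()].
#' @param iter_seed integer iteration seed.
#' @param n population size (ignored when `pop` is supplied).
#' @param spec population specification.
#' @param rates baseline rates.
#' @param rr_table relative-risk table for this iteration (pass a
#'   [sample_relative_risks()] draw for second-order uncertainty).
#' @param coeffs risk-score coefficients.
#' @param years simulated calendar years.
#' @param pop optional pre-built population (shared across scenarios).
#' @param relapse_schedule relapse schedule for policy quitters.
#' @return results-cube slice: `data.table` with columns `year`, `ageband`,
#'   `sex`, `imd_fifth`, `outcome`, `count`.
#' @export
run_iteration <- function(scenario, iter_seed, n = 10000,
                          spec = default_population_spec(),
                          rates = default_baseline_rates(),
                          rr_table = default_relative_risks(),
                          coeffs = default_risk_coefficients(),
                          years = 2011:2030, pop = NULL,
                          relapse_schedule = c(0.30, 0.20, 0.10, 0.05)) {
  if (is.null(pop)) {
    pop <- build_population(spec, n, substream_seed(iter_seed, "pop"))
  } else {
    pop <- copy(pop)
    n <- nrow(pop)
  }
  ctx <- make_ctx(spec, rates, rr_table, coeffs, scenario, iter_seed,
                  years, n, relapse_schedule)
  recs <- vector("list", length(years))
  for (i in seq_along(years)) {
    recs[[i]] <- step_year(pop, ctx, years[i])
    pop <- ctx$pop
  }
  res <- rbindlist(recs)
  setattr(res, "mix_warnings", ctx$mix_warnings %||% 0L)
  setattr(res, "renormalised", ctx$renormalised)
  res
}

#' Second-order Monte Carlo configuration
#'
#' @param n_iterations number of second-order iterations (>= 1). The
#'   package default of 200 stabilises reported medians; tests and examples
#'   use fewer.
#' @param master_seed master seed; per-iteration and per-module sub-streams
#'   are derived deterministically from it.
#' @param sample_rr draw each relative risk per iteration from its
#'   95%-interval log-normal (second-order parameter uncertainty).
#' @param iteration_seeds optional explicit vector of iteration seeds
#'   overriding the derived ones (length `n_iterations`).
#' @return an `mc_config` object.
#' @export
mc_config <- function(n_iterations = 200, master_seed = 1,
                      sample_rr = TRUE, iteration_seeds = NULL) {
  stopifnot(n_iterations >= 1)
  if (!is.null(iteration_seeds)) {
    stopifnot(length(iteration_seeds) == n_iterations)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 master_seed = as.integer(master_seed),
                 sample_rr = isTRUE(sample_rr),
                 iteration_seeds = iteration_seeds),
            class = "mc_config")
}

#' Run the full second-order Monte Carlo design
#'
#' For each iteration, one synthetic population and one draw of the
#' uncertain parameters are shared by every scenario, and all first-order
#' event randomness uses common random numbers across scenarios. The
#' resulting cube carries the iteration axis for downstream summarisation
#' (per-iteration differences, then medians and first/third fourths).
#'
#' @param scenarios a `scenario_config` or list of them.
#' @param mc an [mc_config()].
#' @inheritParams run_iteration
#' @return a `results_cube`: `data.table` with columns `scenario`,
#'   `iteration`, `year`, `ageband`, `sex`, `imd_fifth`, `outcome`,
#'   `count`.
#' @export
run_mc <- function(scenarios, mc = mc_config(), n = 10000,
                   spec = default_population_spec(),
                   rates = default_baseline_rates(),
                   rr_table = default_relative_risks(),
                   coeffs = default_risk_coefficients(),
                   years = 2011:2030,
                   relapse_schedule = c(0.30, 0.20, 0.10, 0.05)) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  nms <- vapply(scenarios, `[[`, "", "name")
  out <- vector("list", mc$n_iterations * length(scenarios))
  k <- 0L
  for (it in seq_len(mc$n_iterations)) {
    iter_seed <- if (!is.null(mc$iteration_seeds)) {
      as.integer(mc$iteration_seeds[it])
    } else {
      substream_seed(mc$master_seed, "iteration", it)
    }
    pop0 <- build_population(spec, n, substream_seed(iter_seed, "pop"))
    rr_it <- if (mc$sample_rr) {
      sample_relative_risks(rr_table, substream_seed(iter_seed, "params"))
    } else rr_table
    for (s in seq_along(scenarios)) {
      cube <- run_iteration(scenarios[[s]], iter_seed, spec = spec,
                            rates = rates, rr_table = rr_it,
                            coeffs = coeffs, years = years, pop = pop0,
                            relapse_schedule = relapse_schedule)
      cube[, `:=`(scenario = nms[s], iteration = it)]
      k <- k + 1L
      out[[k]] <- cube
    }
  }
  res <- rbindlist(out)
  setcolorder(res, c("scenario", "iteration", "year", "ageband", "sex",
                     "imd_fifth", "outcome", "count"))
  setattr(res, "class", c("results_cube", class(res)))
  setattr(res, "years", years)
  res[]
}
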