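# Configuration loading, result persistence, run manifests, defaults
# export, and the observed-vs-simulated validation comparison.

#' Load and validate a YAML configuration
#'
#' Reads a YAML file and dispatches on its `type` field:
#'
#' * `population_spec`: returns a validated [population_spec()]. Strata may
#'   be given as explicit rows or compactly as `ageband_weights` (with
#'   equal sexes and fifths).
#' * `scenario`: returns a validated [scenario_config()]; probability
#'   fields outside `[0, 1]` are rejected with the offending field named.
#' * `run`: returns a run bundle (population path/spec, scenario list, Monte
#'   Carlo settings); a missing `mc` block is filled with defaults and the
#'   injection is noted in the bundle's `notes`.
#'
#' @param path YAML file path.
#' @return a validated configuration object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  type <- cfg$type %||% config_error("type", "missing")
  switch(type,
         population_spec = as_population_spec(cfg),
         scenario = as_scenario_config(cfg),
         run = as_run_config(cfg),
         config_error("type", paste("unknown configuration type", type)))
}

#' Convert a configuration list to a population specification
#'
#' @param cfg list as parsed from YAML.
#' @return a [population_spec()].
#' @export
as_population_spec <- function(cfg) {
  if (!is.null(cfg$strata)) {
    strata <- rbindlist(lapply(cfg$strata, as.data.table))
  } else if (!is.null(cfg$ageband_weights)) {
    w <- unlist(cfg$ageband_weights)
    strata <- CJ(ageband = names(w), sex = c("female", "male"),
                 imd_fifth = 1:5)
    strata[, count := w[ageband] / 10]
  } else {
    config_error("strata", "provide 'strata' rows or 'ageband_weights'")
  }
  factors <- lapply(cfg$factors, function(f) {
    if (!is.null(f$bounds)) f$bounds <- as.numeric(f$bounds)
    f
  })
  population_spec(strata, factors, base_year = cfg$base_year %||% 2011L)
}

#' Convert a configuration list to a scenario configuration
#'
#' @param cfg list as parsed from YAML.
#' @return a [scenario_config()].
#' @export
as_scenario_config <- function(cfg) {
  scr <- NULL
  if (!is.null(cfg$screening)) {
    s <- cfg$screening
    if (!is.null(s$participant_risk_mix) && is.list(s$participant_risk_mix)) {
      s$participant_risk_mix <- unlist(s$participant_risk_mix)
    }
    for (nm in c("statin_uptake", "antihtn_uptake")) {
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    }
    if (!is.null(s$target_fifths)) s$target_fifths <- as.integer(s$target_fifths)
    if (!is.null(s$age_range)) s$age_range <- as.numeric(s$age_range)
    scr <- do.call(screening_policy, s)
  }
  ppol <- if (!is.null(cfg$population_policy)) {
    do.call(population_policy, cfg$population_policy)
  }
  scenario_config(cfg$name %||% config_error("name", "missing"),
                  screening = scr, population_policy = ppol,
                  start_year = cfg$start_year %||% 2011L,
                  diffusion_years = cfg$diffusion_years %||% 5L)
}

as_run_config <- function(cfg) {
  notes <- character(0)
  if (is.null(cfg$mc)) {
    cfg$mc <- list(n_iterations = 200, master_seed = 1)
    notes <- c(notes, "mc block missing; defaults injected")
  }
  mc <- mc_config(n_iterations = cfg$mc$n_iterations %||% 200,
                  master_seed = cfg$mc$master_seed %||% 1,
                  sample_rr = cfg$mc$sample_rr %||% TRUE)
  list(population = cfg$population, scenarios = cfg$scenarios, mc = mc,
       n = cfg$n %||% 10000, notes = notes)
}

#' Write and read a results cube
#'
#' Long-format CSV persistence (columns `scenario`, `iteration`, `year`,
#' `ageband`, `sex`, `imd_fifth`, `outcome`, `count`); the write-read round
#' trip is lossless.
#'
#' @param cube a results cube.
#' @param path CSV file path.
#' @return `read_results` returns the cube `data.table`.
#' @export
write_results <- function(cube, path) {
  fwrite(as.data.table(cube), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- fread(path)
  setattr(out, "class", c("results_cube", class(out)))
  setattr(out, "years", sort(unique(out$year)))
  out[]
}

#' Export a population snapshot to CSV
#'
#' One row per person with a fixed, documented column order: identifiers
#' and demographics first, exposures alphabetically, then disease/vital
#' flags. Lag-buffer and intervention-state columns are included after the
#' flags so a snapshot can be reloaded losslessly.
#'
#' @param pop population `data.table`.
#' @param path CSV file path.
#' @export
export_population <- function(pop, path) {
  lead <- c("id", "age", "sex", "imd_fifth",
            "bmi", "diabetes", "ets", "fv_portions", "pa_days", "sbp",
            "smoking", "tchol", "years_since_quit",
            "chd", "stroke", "alive")
  rest <- setdiff(names(pop), lead)
  fwrite(pop[order(id), c(lead, rest), with = FALSE], path)
  invisible(path)
}

#' Compare simulated with observed CVD deaths
#'
#' Predictive-validation comparison of simulated CVD deaths against a
#' user-supplied observed series: for every overlapping year, the simulated
#' median and first/third fourths across iterations, the observed count,
#' their ratio (simulated median / observed), and whether the observed
#' value falls inside the simulated interquartile range.
#'
#' @param simulated results cube (its `cvd_death` counts are summed per
#'   iteration and year), or a `data.table` with columns `year`,
#'   `iteration`, `deaths`.
#' @param observed `data.table`/data.frame with columns `year`, `deaths`.
#' @return `data.table` with columns `year`, `simulated_median`, `q1`,
#'   `q3`, `observed`, `ratio`, `inside_iqr`.
#' @export
compare_to_observed <- function(simulated, observed) {
  simulated <- as.data.table(simulated)
  observed <- as.data.table(observed)
  if (!"deaths" %in% names(simulated)) {
    simulated <- simulated[outcome == "cvd_death",
                           .(deaths = sum(count)), by = .(year, iteration)]
  }
  yrs <- intersect(unique(simulated$year), unique(observed$year))
  if (length(yrs) == 0) {
    stop("no overlapping years between simulated and observed series",
         call. = FALSE)
  }
  sm <- simulated[year %in% yrs, {
    s <- mc_summary(deaths)
    .(simulated_median = s$median, q1 = s$q1, q3 = s$q3)
  }, by = year]
  out <- merge(sm, observed[year %in% yrs, .(year, observed = deaths)],
               by = "year")
  out[, ratio := simulated_median / observed]
  out[, inside_iqr := observed >= q1 & observed <= q3]
  setorder(out, year)
  out[]
}

#' Run manifest
#'
#' A machine-readable fingerprint sufficient to reproduce a run: hashes of
#' the configuration objects, the master seed, scenario names, iteration
#' count and software versions. Two runs with equal manifests (ignoring
#' `created`) produce identical results cubes.
#'
#' @param spec population specification.
#' @param scenarios list of scenario configurations.
#' @param mc Monte Carlo configuration.
#' @param n population size.
#' @param extra optional named list merged into the manifest (e.g. warning
#'   counts).
#' @return named list.
#' @export
run_manifest <- function(spec, scenarios, mc, n, extra = list()) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  c(list(
    config_hash = config_hash(list(spec = spec, scenarios = scenarios,
                                   mc = mc, n = n)),
    master_seed = mc$master_seed,
    n_iterations = mc$n_iterations,
    n = n,
    scenarios = vapply(scenarios, `[[`, "", "name"),
    package_version = as.character(packageVersion("cvdmicrosim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
}

#' Write the shipped default tables for editing
#'
#' Emits the editable defaults - relative risks, baseline rates, risk-score
#' coefficients, the England-like population specification and the eight
#' canned scenario files - into a directory.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
dump_defaults <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    rr = file.path(dir, "relative_risks.csv"),
    inc = file.path(dir, "incidence.csv"),
    cf = file.path(dir, "case_fatality.csv"),
    oth = file.path(dir, "other_mortality.csv"),
    coeffs = file.path(dir, "risk_score_coefficients.yaml"),
    pop = file.path(dir, "population_spec.yaml")
  )
  rates <- default_baseline_rates()
  fwrite(default_relative_risks(), paths[["rr"]], na = "NA")
  fwrite(rates$incidence, paths[["inc"]])
  fwrite(rates$case_fatality, paths[["cf"]])
  fwrite(rates$other_mortality, paths[["oth"]])
  yaml::write_yaml(default_risk_coefficients(), paths[["coeffs"]])
  yaml::write_yaml(population_spec_to_list(default_population_spec()),
                   paths[["pop"]])
  scen <- c(list(baseline = scenario_baseline(),
                 universal_screening = scenario_universal_screening(),
                 concentrated_screening = scenario_concentrated_screening(),
                 population_wide = scenario_population_wide(),
                 combined = scenario_combined()),
            sensitivity_scenarios())
  for (nm in names(scen)) {
    p <- file.path(dir, paste0("scenario_", nm, ".yaml"))
    yaml::write_yaml(scenario_config_to_list(scen[[nm]]), p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @rdname dump_defaults
#' @param spec a [population_spec()].
#' @export
population_spec_to_list <- function(spec) {
  strata <- split(spec$strata, seq_len(nrow(spec$strata)))
  list(type = "population_spec",
       base_year = spec$base_year,
       strata = unname(lapply(strata, as.list)),
       factors = spec$factors)
}

#' @rdname dump_defaults
#' @param scenario a [scenario_config()].
#' @export
scenario_config_to_list <- function(scenario) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  out <- list(type = "scenario",
              name = scenario$name,
              start_year = scenario$start_year,
              diffusion_years = scenario$diffusion_years)
  if (!is.null(scenario$screening)) {
    s <- strip(scenario$screening)
    if (is.numeric(s$participant_risk_mix)) {
      s$participant_risk_mix <- as.list(s$participant_risk_mix)
    }
    s$statin_uptake <- as.list(s$statin_uptake)
    s$antihtn_uptake <- as.list(s$antihtn_uptake)
    out$screening <- s
  }
  if (!is.null(scenario$population_policy)) {
    out$population_policy <- strip(scenario$population_policy)
  }
  out
}
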