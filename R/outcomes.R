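# Outcome metrics: cases/deaths prevented or postponed, absolute and
# relative equity slope indices, the equity summary chart, and Monte Carlo
# summaries.

# Fractional-rank midpoints of population-quintile deprivation fifths,
# ordered least -> most deprived: the standard slope-index-of-inequality
# regressor with equal fifth weights.
RANK_MIDPOINTS <- seq(0.1, 0.9, by = 0.2)

cube_outcomes <- function(outcome) {
  switch(outcome,
         cases = c("chd_case", "stroke_case"),
         deaths = "cvd_death",
         outcome)
}

#' Cases or deaths prevented or postponed
#'
#' Per-iteration difference in cumulative event counts between the baseline
#' cube and a scenario cube over the summary window (2016-2030 by default,
#' when interventions begun in 2011 first reach the five-year exposure
#' lag). Values may be negative in some iterations. With
#' `by = "imd_fifth"` the difference is stratified by deprivation fifth;
#' marginal CPP equals the sum of the stratum values.
#'
#' @param baseline_cube,scenario_cube results cubes sharing iteration axis
#'   and strata (long format as produced by [run_mc()], or any
#'   `data.table` with the same columns).
#' @param outcome `"cases"` (first-ever CHD + stroke), `"deaths"` (CVD
#'   deaths), or any single cube outcome name.
#' @param by optional stratification column(s) (e.g. `"imd_fifth"`).
#' @param years summary window.
#' @return `data.table` with columns `iteration`, the `by` columns and
#'   `cpp`.
#' @export
cpp <- function(baseline_cube, scenario_cube, outcome = "cases",
                by = NULL, years = 2016:2030) {
  outs <- cube_outcomes(outcome)
  agg <- function(cube) {
    cube <- as.data.table(cube)
    need <- c("iteration", "year", "outcome", "count", by)
    miss <- setdiff(need, names(cube))
    if (length(miss)) {
      stop("cube lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cube[year %in% years & outcome %in% outs,
         .(total = sum(count)), by = c("iteration", by)]
  }
  b <- agg(baseline_cube)
  s <- agg(scenario_cube)
  if (!setequal(b$iteration, s$iteration)) {
    stop("baseline and scenario cubes have mismatched iteration axes",
         call. = FALSE)
  }
  # complete missing strata with zero counts before differencing
  keys <- c("iteration", by)
  full <- unique(rbind(b[, ..keys], s[, ..keys]))
  b <- b[full, on = keys]; b[is.na(total), total := 0]
  s <- s[full, on = keys]; s[is.na(total), total := 0]
  out <- b[s, on = keys]
  out <- out[, .(cpp = total - i.total), by = keys]
  setorderv(out, keys)
  out[]
}

ols_slope <- function(y, x) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

as_fifth_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  x
}

#' Absolute equity slope index
#'
#' Ordinary-least-squares slope of cases (or deaths) prevented or postponed
#' per deprivation fifth on the fractional-rank midpoints (0.1, 0.3, 0.5,
#' 0.7, 0.9, least to most deprived). Positive values mean more events
#' prevented or postponed in more deprived fifths - the intervention
#' reduces absolute inequality. Computed per Monte Carlo iteration and
#' summarised afterwards.
#'
#' @param cpp_by_fifth numeric vector of five CPP values ordered least to
#'   most deprived, or a matrix/data.frame with five columns (rows =
#'   iterations).
#' @param rank_midpoints regressor values for the five fifths.
#' @return slope (CPP units per unit rank range), one value per row.
#' @export
absolute_equity_slope_index <- function(cpp_by_fifth,
                                        rank_midpoints = RANK_MIDPOINTS) {
  m <- as_fifth_matrix(cpp_by_fifth)
  if (ncol(m) != 5 || anyNA(m)) {
    stop("cpp_by_fifth must provide five non-missing values per iteration",
         call. = FALSE)
  }
  out <- apply(m, 1, ols_slope, x = rank_midpoints)
  if (is.vector(cpp_by_fifth) && length(cpp_by_fifth) == 5) out[[1]] else
    unname(out)
}

#' Relative equity slope index
#'
#' Accounts for the pre-existing socioeconomic gradient of disease burden:
#' each fifth's CPP is first converted to a relative percentage reduction
#' of that fifth's baseline burden (`100 * cpp / baseline_cases`), and the
#' index is the OLS slope of these percentages on the fractional-rank
#' midpoints. Positive values mean the intervention reduces relative
#' inequality.
#'
#' @param cpp_by_fifth five CPP values (or iteration rows), least to most
#'   deprived.
#' @param baseline_by_fifth five positive baseline cumulative counts (or
#'   iteration rows).
#' @param rank_midpoints regressor values.
#' @return slope in percentage points per unit rank range.
#' @export
relative_equity_slope_index <- function(cpp_by_fifth, baseline_by_fifth,
                                        rank_midpoints = RANK_MIDPOINTS) {
  mc <- as_fifth_matrix(cpp_by_fifth)
  mb <- as_fifth_matrix(baseline_by_fifth)
  if (nrow(mb) == 1 && nrow(mc) > 1) mb <- mb[rep(1, nrow(mc)), , drop = FALSE]
  if (any(mb <= 0)) {
    stop("baseline counts must be positive in every fifth", call. = FALSE)
  }
  rel <- 100 * mc / mb
  out <- apply(rel, 1, ols_slope, x = rank_midpoints)
  if (is.vector(cpp_by_fifth) && length(cpp_by_fifth) == 5) out[[1]] else
    unname(out)
}

#' Height of the equity curve at a given total effectiveness
#'
#' The equity curve is the locus of zero change in relative inequality:
#' a total CPP allocated across fifths proportionally to their baseline
#' burden shares leaves relative inequality untouched, and the curve height
#' is the absolute equity slope index of that proportional allocation.
#' Interventions plotted above the curve decrease relative inequality;
#' below it they increase it. The height is linear in the total.
#'
#' @param total_cpp non-negative total CPP (vectorised).
#' @param baseline_by_fifth five baseline cumulative counts, least to most
#'   deprived.
#' @param rank_midpoints regressor values.
#' @return curve height in CPP units.
#' @export
equity_curve_point <- function(total_cpp, baseline_by_fifth,
                               rank_midpoints = RANK_MIDPOINTS) {
  shares <- baseline_by_fifth / sum(baseline_by_fifth)
  slope1 <- ols_slope(shares, rank_midpoints)
  total_cpp * slope1
}

#' Median and interquartile range of per-iteration values
#'
#' Summarises a Monte Carlo sample by its median and first/third fourths
#' (quartiles), using linear interpolation between order statistics
#' (`stats::quantile` type 7), the package's fixed quantile convention.
#'
#' @param samples numeric vector (>= 1 value).
#' @return named list `median`, `q1`, `q3`.
#' @export
mc_summary <- function(samples) {
  if (length(samples) == 0) stop("no samples to summarise", call. = FALSE)
  q <- unname(quantile(samples, c(0.25, 0.5, 0.75), type = 7, na.rm = FALSE))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Equity summary for a scenario
#'
#' Computes, per Monte Carlo iteration, the CPP by deprivation fifth, the
#' total CPP, the absolute and relative equity slope indices and the equity
#' curve height at the iteration's total, then summarises each by median
#' and first/third fourths. Indices are always computed per iteration and
#' summarised afterwards, never the other way round.
#'
#' @param baseline_cube,scenario_cube results cubes sharing axes.
#' @param outcome `"cases"` or `"deaths"`.
#' @param years summary window.
#' @return list with `per_iteration` (`data.table`) and `summary` (named
#'   list of [mc_summary()] results plus `cpp_by_fifth` medians).
#' @export
equity_summary <- function(baseline_cube, scenario_cube, outcome = "cases",
                           years = 2016:2030) {
  outs <- cube_outcomes(outcome)
  d <- cpp(baseline_cube, scenario_cube, outcome = outcome,
           by = "imd_fifth", years = years)
  bl <- as.data.table(baseline_cube)[
    year %in% years & outcome %in% outs,
    .(baseline = sum(count)), by = .(iteration, imd_fifth)]
  # complete all five fifths in every iteration (zero counts for strata
  # that recorded no events)
  full <- CJ(iteration = unique(d$iteration), imd_fifth = 1:5)
  d <- d[full, on = c("iteration", "imd_fifth")][is.na(cpp), cpp := 0]
  bl <- bl[full, on = c("iteration", "imd_fifth")][is.na(baseline),
                                                   baseline := 0]
  wide <- dcast(d, iteration ~ imd_fifth, value.var = "cpp")
  bwide <- dcast(bl, iteration ~ imd_fifth, value.var = "baseline")
  setorder(wide, iteration); setorder(bwide, iteration)
  cpp_m <- as.matrix(wide[, -1])
  bl_m <- as.matrix(bwide[, -1])
  rel <- if (all(bl_m > 0)) {
    relative_equity_slope_index(cpp_m, bl_m)
  } else {
    warning("zero baseline counts in some fifth; relative equity slope ",
            "index not computed", call. = FALSE)
    rep(NA_real_, nrow(cpp_m))
  }
  per <- data.table(
    iteration = wide$iteration,
    total_cpp = rowSums(cpp_m),
    absolute_index = absolute_equity_slope_index(cpp_m),
    relative_index = rel
  )
  per[, curve_height := vapply(seq_len(.N), function(i) {
    equity_curve_point(max(total_cpp[i], 0), bl_m[i, ])
  }, numeric(1))]
  list(
    per_iteration = cbind(per, as.data.table(cpp_m)),
    summary = list(
      total_cpp = mc_summary(per$total_cpp),
      absolute_index = mc_summary(per$absolute_index),
      relative_index = if (anyNA(per$relative_index)) {
        list(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      } else {
        mc_summary(per$relative_index)
      },
      cpp_by_fifth = apply(cpp_m, 2, median)
    )
  )
}

#' Equity summary chart data
#'
#' Assembles the coordinates of the equity summary chart: one point per
#' scenario (median total CPP on the horizontal axis, median absolute
#' equity slope index on the vertical axis, with first/third-fourth error
#' bars) and the equity curve traced through the origin. Returned as plain
#' data suitable for JSON serialisation or plotting.
#'
#' @param baseline_cube baseline results cube.
#' @param scenario_cubes named list of scenario cubes.
#' @param outcome `"cases"` or `"deaths"`.
#' @param years summary window.
#' @return list with `points` (`data.table`) and `curve` (`data.table` of
#'   `total_cpp`, `height`).
#' @export
equity_chart_data <- function(baseline_cube, scenario_cubes,
                              outcome = "cases", years = 2016:2030) {
  pts <- rbindlist(lapply(names(scenario_cubes), function(nm) {
    es <- equity_summary(baseline_cube, scenario_cubes[[nm]],
                         outcome = outcome, years = years)
    s <- es$summary
    data.table(scenario = nm,
               total_cpp = s$total_cpp$median,
               total_q1 = s$total_cpp$q1, total_q3 = s$total_cpp$q3,
               absolute_index = s$absolute_index$median,
               abs_q1 = s$absolute_index$q1, abs_q3 = s$absolute_index$q3,
               relative_index = s$relative_index$median)
  }))
  outs <- cube_outcomes(outcome)
  bl <- as.data.table(baseline_cube)[
    year %in% years & outcome %in% outs,
    .(baseline = sum(count)), by = imd_fifth]
  setorder(bl, imd_fifth)
  xmax <- max(pts$total_cpp, 1)
  grid <- seq(0, 1.2 * xmax, length.out = 25)
  curve <- data.table(total_cpp = grid,
                      height = equity_curve_point(grid, bl$baseline))
  list(points = pts, curve = curve)
}
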