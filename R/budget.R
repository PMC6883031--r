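# non-breeding season: September (outbound), October-February (wintering),
# March (return); non-leap month lengths
SEASON_MONTHS <- c(9L, 10L, 11L, 12L, 1L, 2L, 3L)
SEASON_DAYS <- c(30L, 31L, 30L, 31L, 31L, 28L, 31L)

#' Define a migratory strategy scenario
#'
#' @param name one of `"current"`, `"transarctic"`, `"residency"` (free
#'   text allowed).
#' @param colony `c(lon, lat)` of the breeding colony.
#' @param wintering `c(lon, lat)` of the wintering location.
#' @param outbound September route (a `route`), or `NULL` for a degenerate
#'   zero-length journey.
#' @param return_route March route; defaults to the outbound route (the
#'   spring journey reuses the autumn one unless a peripheral variant is
#'   supplied).
#' @param feasible `FALSE` marks a strategy that cannot be realized for
#'   this climate member (e.g. no residency area).
#' @return an object of class `strategy_scenario`.
#' @export
strategy_scenario <- function(name, colony, wintering, outbound = NULL,
                              return_route = outbound, feasible = TRUE) {
  structure(list(name = name, colony = colony, wintering = wintering,
                 outbound = outbound, return_route = return_route,
                 feasible = feasible),
            class = "strategy_scenario")
}

#' Mean daily energy for one strategy month
#'
#' Wintering months (Oct-Feb) use the monthly environment at the wintering
#' location with the default non-flying activity budget. Migration months
#' (Sept and Mar) use the route-averaged environment, with the flying
#' fraction from [flight_time_fraction()] and the remainder split by the
#' default budget. An infeasible strategy yields a result flagged
#' `feasible = FALSE` rather than an error.
#'
#' @param scenario a [strategy_scenario()].
#' @param month calendar month within September-March.
#' @param member climate member.
#' @param world a [make_synthetic_world()] result.
#' @param bird a [bird_spec()].
#' @param world_scenario `"baseline"` or `"future"`.
#' @param rest_budget non-flying time split `c(on_water, rest_air)`.
#' @param wind,cloud ambient wind (m/s) and cloud fraction for the
#'   microclimate.
#' @param speed_ms,duration_days migration speed and window.
#' @return list with `kj_day`, `flight_fraction`, `feasible`.
#' @export
scenario_month_energy <- function(scenario, month, member, world, bird,
                                  world_scenario = "future",
                                  rest_budget = c(on_water = 0.9,
                                                  rest_air = 0.1),
                                  wind = 6, cloud = 0.6, speed_ms = 13,
                                  duration_days = 30) {
  if (!month %in% SEASON_MONTHS) stop("month outside September-March")
  if (!isTRUE(scenario$feasible)) {
    return(list(kj_day = NA_real_, flight_fraction = NA_real_,
                feasible = FALSE))
  }
  year <- world$years[[world_scenario]]
  migration <- month %in% c(9L, 3L)
  if (migration) {
    route <- if (month == 9L) scenario$outbound else scenario$return_route
    if (is.null(route) || route$total_km == 0) {
      env <- extract_env(world, scenario$wintering[1], scenario$wintering[2],
                         year, month, c("airtemp", "sst"), member)
      f <- 0
    } else {
      env <- route_env_average(route, world, month, member, world_scenario,
                               c("airtemp", "sst"))
      f <- flight_time_fraction(route$total_km, speed_ms, duration_days)
    }
  } else {
    env <- extract_env(world, scenario$wintering[1], scenario$wintering[2],
                       year, month, c("airtemp", "sst"), member)
    f <- 0
  }
  wt <- if (is.na(env[["sst"]])) max(env[["airtemp"]], -1.8) else env[["sst"]]
  mc <- microclimate(airtemp = env[["airtemp"]], watertemp = wt, wind = wind,
                     cloud = cloud, shortwave = 0)
  budget <- c(flying = f, on_water = (1 - f) * rest_budget[["on_water"]],
              rest_air = (1 - f) * rest_budget[["rest_air"]])
  e <- daily_energy(bird, mc, budget)
  list(kj_day = e$kj_day, flight_fraction = f, feasible = TRUE)
}

#' Full September-March daily-energy series for a strategy
#'
#' @inheritParams scenario_month_energy
#' @param ... passed to [scenario_month_energy()].
#' @return data frame `month, days, kj_day, flight_fraction` (or a
#'   `feasible = FALSE` stub).
#' @export
strategy_month_series <- function(scenario, member, world, bird,
                                  world_scenario = "future", ...) {
  if (!isTRUE(scenario$feasible)) {
    return(structure(data.frame(month = SEASON_MONTHS, days = SEASON_DAYS,
                                kj_day = NA_real_,
                                flight_fraction = NA_real_),
                     feasible = FALSE))
  }
  res <- lapply(SEASON_MONTHS, function(m) {
    scenario_month_energy(scenario, m, member, world, bird, world_scenario,
                          ...)
  })
  structure(data.frame(month = SEASON_MONTHS, days = SEASON_DAYS,
                       kj_day = vapply(res, `[[`, numeric(1), "kj_day"),
                       flight_fraction = vapply(res, `[[`, numeric(1),
                                                "flight_fraction")),
            feasible = TRUE)
}

#' Seasonal total from a monthly series
#'
#' `sum(daily * days) / 1000` MJ over the complete 212-day
#' September-to-March season (non-leap February).
#'
#' @param series data frame with `month` and `kj_day` (as from
#'   [strategy_month_series()]).
#' @return total energy in MJ.
#' @export
total_budget <- function(series) {
  if (!all(SEASON_MONTHS %in% series$month)) {
    stop("series must cover September-March")
  }
  k <- match(SEASON_MONTHS, series$month)
  kj <- series$kj_day[k]
  if (anyNA(kj)) stop("missing monthly value")
  sum(kj * SEASON_DAYS) / 1000
}

#' Climate-member ensemble statistics for one strategy
#'
#' Mean and sample standard deviation (n - 1; zero when a single member) of
#' the per-month daily energies and of the seasonal total, over feasible
#' members only; infeasible members are recorded in `excluded`.
#'
#' @param series_by_member named list of [strategy_month_series()] results.
#' @return an object of class `energy_budget`.
#' @export
ensemble_stats <- function(series_by_member) {
  feas <- vapply(series_by_member, function(s) isTRUE(attr(s, "feasible")),
                 logical(1))
  if (!any(feas)) stop("no feasible climate member")
  used <- series_by_member[feas]
  kj <- sapply(used, function(s) s$kj_day[match(SEASON_MONTHS, s$month)])
  kj <- matrix(kj, nrow = length(SEASON_MONTHS))
  totals <- vapply(used, total_budget, numeric(1))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(
    list(months = SEASON_MONTHS,
         kj_day_mean = rowMeans(kj),
         kj_day_sd = apply(kj, 1, sd0),
         total_mj = totals,
         total_mean = mean(totals),
         total_sd = sd0(totals),
         members = names(used),
         excluded = names(series_by_member)[!feas]),
    class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> total %.1f +/- %.1f MJ over %d member(s)\n",
              x$total_mean, x$total_sd, length(x$members)))
  if (length(x$excluded)) {
    cat("  infeasible members:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare strategies by seasonal energy total
#'
#' @param budgets named list of [ensemble_stats()] results, one per
#'   strategy.
#' @return list with `table` (strategy, total mean, SD, rank), `ratios`
#'   (matrix of mean-total ratios, row / column; `NULL` for a single
#'   strategy) and `ranking` (cheapest first).
#' @export
compare_strategies <- function(budgets) {
  tb <- data.frame(strategy = names(budgets),
                   total_mean_mj = vapply(budgets, `[[`, numeric(1),
                                          "total_mean"),
                   total_sd_mj = vapply(budgets, `[[`, numeric(1),
                                        "total_sd"))
  tb$rank <- rank(tb$total_mean_mj, ties.method = "min")
  ratios <- NULL
  if (nrow(tb) >= 2L) {
    ratios <- outer(tb$total_mean_mj, tb$total_mean_mj, "/")
    dimnames(ratios) <- list(tb$strategy, tb$strategy)
  }
  list(table = tb, ratios = ratios,
       ranking = tb$strategy[order(tb$total_mean_mj)])
}

#' Write a strategy comparison as CSV, JSON and Markdown
#'
#' @param comparison a [compare_strategies()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(comparison$table, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(table = comparison$table,
         ratios = comparison$ratios, ranking = comparison$ranking),
    file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", matrix = "rowmajor")
  md <- c("# Strategy comparison", "",
          "| strategy | total (MJ) | SD (MJ) | rank |",
          "|---|---|---|---|",
          sprintf("| %s | %.1f | %.1f | %d |", comparison$table$strategy,
                  comparison$table$total_mean_mj,
                  comparison$table$total_sd_mj, comparison$table$rank),
          "", paste("Cheapest strategy:", comparison$ranking[1]))
  writeLines(md, file.path(dir, "comparison.md"))
  invisible(dir)
}
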