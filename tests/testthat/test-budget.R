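mk_series <- function(kj) {
  structure(data.frame(month = c(9:12, 1:3), days = c(30, 31, 30, 31, 31,
                                                      28, 31),
                       kj_day = kj, flight_fraction = 0),
            feasible = TRUE)
}

mk_budget <- function(total_mean, total_sd = 0) {
  structure(list(months = c(9:12, 1:3), kj_day_mean = rep(total_mean, 7),
                 kj_day_sd = rep(0, 7), total_mj = total_mean,
                 total_mean = total_mean, total_sd = total_sd,
                 members = "m1", excluded = character()),
            class = "energy_budget")
}

test_that("seasonal totals integrate over the 212-day season", {
  expect_equal(total_budget(mk_series(rep(1000, 7))), 212)
  expect_equal(total_budget(mk_series(rep(0, 7))), 0)
  # linear ramp consistent with the published Barents Sea total
  ramp <- seq(732, 772, length.out = 7)
  total <- total_budget(mk_series(ramp))
  expect_equal(total, 159.5, tolerance = 0.01)
  expect_lt(abs(total - 161) / 161, 0.02)
  expect_error(total_budget(mk_series(rep(1000, 7))[-1, ]), "September")
  bad <- mk_series(rep(1000, 7)); bad$kj_day[3] <- NA
  expect_error(total_budget(bad), "missing")
})

test_that("ensemble statistics use the sample SD and exclude infeasible members", {
  s1 <- mk_series(rep(100000 / 212, 7))   # total 100 MJ
  s2 <- mk_series(rep(120000 / 212, 7))   # total 120 MJ
  st <- ensemble_stats(list(m1 = s1, m2 = s2))
  expect_equal(st$total_mean, 110)
  expect_equal(st$total_sd, sd(c(100, 120)), tolerance = 1e-9)
  expect_equal(st$total_sd, 14.142, tolerance = 1e-3)
  # a single member has zero SD by convention
  one <- ensemble_stats(list(m1 = s1))
  expect_equal(one$total_sd, 0)
  # infeasible members are excluded and recorded
  bad <- structure(s1, feasible = FALSE)
  st2 <- ensemble_stats(list(m1 = s1, m2 = bad, m3 = s2))
  expect_identical(st2$excluded, "m2")
  expect_identical(st2$members, c("m1", "m3"))
  expect_equal(st2$total_mean, 110)
  expect_error(ensemble_stats(list(a = bad)), "no feasible")
})

test_that("identical members give zero SD throughout", {
  s <- mk_series(rep(500, 7))
  st <- ensemble_stats(list(m1 = s, m2 = s))
  expect_true(all(st$kj_day_sd == 0))
  expect_equal(st$total_sd, 0)
})

test_that("strategy comparison reports ratios and rankings", {
  cmp <- compare_strategies(list(transarctic = mk_budget(59, 0.7),
                                 residency = mk_budget(159, 0.3)))
  expect_equal(cmp$ratios["transarctic", "residency"], 59 / 159)
  expect_equal(round(cmp$ratios["transarctic", "residency"], 2), 0.37)
  expect_identical(cmp$ranking[1], "transarctic")
  same <- compare_strategies(list(a = mk_budget(100), b = mk_budget(100)))
  expect_true(all(same$ratios == 1))
  single <- compare_strategies(list(a = mk_budget(100)))
  expect_null(single$ratios)
  expect_identical(nrow(single$table), 1L)
})

test_that("monthly strategy energies react to wintering temperature", {
  w <- demo_world()
  colony <- c(55, 77)
  # colder vs warmer wintering cell, all else equal
  cold <- strategy_scenario("cold", colony, c(-31.5, 53.75))
  warm <- strategy_scenario("warm", colony, c(148.5, 53.75))
  b <- bird_spec()
  e_cold <- scenario_month_energy(cold, 1, "m1", w, b)
  e_warm <- scenario_month_energy(warm, 1, "m1", w, b)
  t_cold <- extract_env(w, -31.5, 53.75, 2055, 1, "airtemp")
  t_warm <- extract_env(w, 148.5, 53.75, 2055, 1, "airtemp")
  expect_lt(t_cold, t_warm)   # the Pacific winter-warm sector
  expect_gt(e_cold$kj_day, e_warm$kj_day)
  # degenerate zero-length migration equals the wintering computation
  res <- strategy_scenario("residency", colony, colony)
  e_sept <- scenario_month_energy(res, 9, "m1", w, b)
  e_ref <- scenario_month_energy(res, 10, "m1", w, b)
  expect_equal(e_sept$flight_fraction, 0)
  # infeasible strategies yield a flagged result, not an error
  inf <- strategy_scenario("residency", colony, colony, feasible = FALSE)
  out <- scenario_month_energy(inf, 12, "m1", w, b)
  expect_false(out$feasible)
  expect_true(is.na(out$kj_day))
  expect_error(scenario_month_energy(res, 5, "m1", w, b),
               "September-March")
})

test_that("full month series carries flight costs only in migration months", {
  w <- demo_world()
  colony <- c(55, 77)
  dest <- c(148.5, 53.75)
  r <- direct_route(colony, dest, w, 9, "m1", "future")
  sc <- strategy_scenario("transarctic", colony, dest, r)
  ser <- strategy_month_series(sc, "m1", w, bird_spec())
  expect_identical(ser$month, c(9L, 10L, 11L, 12L, 1L, 2L, 3L))
  expect_true(all(ser$flight_fraction[ser$month %in% c(9, 3)] > 0))
  expect_true(all(ser$flight_fraction[!ser$month %in% c(9, 3)] == 0))
  expect_true(all(is.finite(ser$kj_day)))
  expect_true(isTRUE(attr(ser, "feasible")))
})
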