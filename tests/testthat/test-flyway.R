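test_that("route graphs have 8-neighbour topology and exact edge lengths", {
  w <- ocean_world(spacing = 2, lat = c(56, 64), lon = c(-4, 6))
  g <- route_graph(w, 1)
  deg <- table(g$edges$from)
  nlat <- length(w$lat); nlon <- length(w$lon)
  interior <- (2 - 1) * nlat + 2   # cell (2, 2)
  expect_identical(unname(deg[as.character(interior)]), 8L)
  expect_identical(unname(deg["1"]), 3L)   # corner node
  # E-W edge at 60N: small-arc approximation within 0.1% of haversine
  i60 <- which.min(abs(w$lat - 60))
  from <- (1 - 1) * nlat + i60; to <- (2 - 1) * nlat + i60
  len <- g$edges$length_km[g$edges$from == from & g$edges$to == to]
  approx_len <- cos(w$lat[i60] * pi / 180) * 111.195 * 2
  expect_lt(abs(len - approx_len) / len, 0.001)
})

test_that("unobstructed direct routes follow the great circle", {
  w <- ocean_world(spacing = 1, lat = c(50, 70), lon = c(-10, 10))
  r <- direct_route(c(-5, 55), c(5, 65), w, 9)
  gc <- gc_distance(-5, 55, 5, 65)
  expect_lt(abs(r$total_km - gc) / gc, 0.01)
  expect_false(any(r$legs$land))
  expect_equal(r$total_km, sum(r$legs$length_km))
})

test_that("narrow land corridors are crossed, wide ones are detoured", {
  # 80 km corridor: constraint inactive, great circle accepted
  w_narrow <- patterned_world(function(lon, lat) lon > 0 & lon < 0.7,
                              spacing = 0.35, lat = c(59, 64),
                              lon = c(-2, 2.5), seed = 3)
  r <- direct_route(c(-1.5, 61.5), c(2, 61.5), w_narrow, 9)
  run <- polarflyway:::max_land_run(r$legs)
  expect_lte(run, 100)
  expect_gt(run, 0)
  gc <- gc_distance(-1.5, 61.5, 2, 61.5)
  expect_lt(abs(r$total_km - gc) / gc, 0.01)

  # thick barrier with a strait: the route deviates through the strait
  w <- strait_world()
  r2 <- direct_route(c(55, 55), c(63, 55), w, 9)
  expect_gt(r2$total_km, gc_distance(55, 55, 63, 55))
  expect_lte(polarflyway:::max_land_run(r2$legs), 100)
  expect_true(any(abs(r2$waypoints$lat - 59) < 1))   # passes the strait
})

test_that("constrained routes equal brute-force optima on toy grids", {
  worlds <- list(
    strait_world(),
    # 4x4 with a partial barrier
    patterned_world(function(lon, lat) lon > 0.5 & lon < 3.5 & lat < 62,
                    spacing = 1.5, lat = c(58, 64), lon = c(-1, 5),
                    seed = 4),
    # 4x4 open ocean
    ocean_world(spacing = 1.5, lat = c(58, 64), lon = c(0, 6), seed = 5))
  for (w in worlds) {
    nlat <- length(w$lat); nlon <- length(w$lon)
    expect_lte(nlat, 5); expect_lte(nlon, 5)
    from <- c(1, 1); to <- c(nlat, nlon)
    r <- direct_route(c(w$lon[from[2]], w$lat[from[1]]),
                      c(w$lon[to[2]], w$lat[to[1]]), w, 9)
    best <- brute_force_route_cost(w, from, to, 9)
    if (!any(r$legs$land)) {
      # unconstrained great-circle case: route may undercut the grid path
      expect_lte(r$total_km, best + 1e-6)
    } else {
      expect_equal(r$total_km, best, tolerance = 1e-9)
    }
    # peripheral with beta = 0 reduces to the shortest constrained path
    p0 <- peripheral_route(c(w$lon[from[2]], w$lat[from[1]]),
                           c(w$lon[to[2]], w$lat[to[1]]), w, 9, beta = 0)
    expect_equal(p0$total_km, best, tolerance = 1e-9)
    # ice-penalized optimum matches brute force too
    pb <- peripheral_route(c(w$lon[from[2]], w$lat[from[1]]),
                           c(w$lon[to[2]], w$lat[to[1]]), w, 1, beta = 10)
    cost <- sum(pb$legs$length_km * (1 + 10 * (pb$legs$ice >= 0.5)))
    expect_equal(cost, brute_force_route_cost(w, from, to, 1, beta = 10),
                 tolerance = 1e-9)
  }
})

test_that("route cost is symmetric under endpoint reversal", {
  w <- strait_world()
  a <- c(55, 55); b <- c(63, 55)
  r1 <- direct_route(a, b, w, 9)
  r2 <- direct_route(b, a, w, 9)
  expect_equal(r1$total_km, r2$total_km, tolerance = 1e-9)
})

test_that("peripheral routes avoid dense ice when possible", {
  # polar cap of dense ice; endpoints sit one row inside the cap edge, so
  # dipping to the open southern periphery is the cheap option
  w <- ocean_world(spacing = 1, lat = c(55, 75), lon = c(-12, 12), seed = 6)
  f <- w$fields$m1$baseline$ice
  cap <- outer(w$lat > 64, rep(TRUE, length(w$lon))) == 1
  for (m in 1:12) {
    sl <- f$values[m, , ]
    sl[cap] <- 0.95; sl[!cap] <- 0.05
    f$values[m, , ] <- sl
  }
  w$fields$m1$baseline$ice <- f
  a <- c(-10, 64.8); b <- c(10, 64.8)
  d <- direct_route(a, b, w, 1)
  p <- peripheral_route(a, b, w, 1, beta = 10)
  expect_gt(d$ice_km, 0)
  expect_lt(p$ice_km, d$ice_km)   # skirts all but the cap entry/exit
  expect_lt(p$ice_km, 0.5 * d$ice_km)
  expect_gt(p$total_km, d$total_km)
  # route dips below the cap edge
  expect_lt(min(p$waypoints$lat), 64)
  # without ice anywhere the peripheral solution collapses to the direct one
  w0 <- ocean_world(spacing = 1, lat = c(55, 75), lon = c(-12, 12), seed = 6)
  for (m in 1:12) w0$fields$m1$baseline$ice$values[m, , ] <- 0
  p0 <- peripheral_route(a, b, w0, 1, beta = 10)
  d0 <- direct_route(a, b, w0, 1)
  expect_equal(p0$ice_km, 0)
  # grid path vs great-circle polyline: same corridor, small discretization gap
  expect_lt(abs(p0$total_km - d0$total_km) / d0$total_km, 0.08)
})

test_that("peripheral ice exposure never exceeds the shortest path's", {
  # optimality corollary: with any positive penalty the ice-exposed length
  # of the peripheral path cannot exceed that of the zero-penalty shortest
  # path through the same graph
  for (seed in 1:4) {
    w <- patterned_world(function(lon, lat) lon > 8 & lat < 62, spacing = 1,
                         lat = c(55, 70), lon = c(-12, 12), seed = seed,
                         warming = 2)
    a <- c(-10, 57); b <- c(6, 68)
    p0 <- peripheral_route(a, b, w, 1, beta = 0)
    p <- peripheral_route(a, b, w, 1, beta = 10)
    expect_lte(p$ice_km, p0$ice_km + 1e-9)
  }
})

test_that("route environments average with leg-length weights", {
  w <- ocean_world(spacing = 0.5, lat = c(49, 56), lon = c(-2, 2), seed = 7)
  # two-level field: 0 south of 51N, 8 north of it
  f <- w$fields$m1$baseline$airtemp
  split <- outer(w$lat > 51, rep(TRUE, length(w$lon))) == 1
  for (m in 1:12) {
    sl <- f$values[m, , ]
    sl[split] <- 8; sl[!split] <- 0
    f$values[m, , ] <- sl
  }
  w$fields$m1$baseline$airtemp <- f
  # legs of ~100 km (region 0) and ~300 km (region 8) along the meridian
  wp <- data.frame(lon = 0, lat = c(50, 50 + 100 / 111.1949,
                                    50 + 400 / 111.1949))
  r <- polarflyway:::route_obj(wp, w, 1, "m1", "baseline", "direct")
  out <- route_env_average(r, w, 1, variables = "airtemp")
  expect_equal(unname(out), 6, tolerance = 1e-3)
  # uniform fields average to themselves
  w_const <- set_constant_field(w, "sst", 4)
  u2 <- route_env_average(r, w_const, 1, variables = "sst")
  expect_equal(unname(u2), 4)
})

test_that("flight-time fractions follow the one-month 13 m/s rule", {
  expect_equal(flight_time_fraction(0), 0)
  expect_equal(flight_time_fraction(2000), 0.0594, tolerance = 1e-3)
  expect_equal(flight_time_fraction(10000), 0.2968, tolerance = 1e-3)
  expect_error(flight_time_fraction(40000), "infeasible")
  expect_error(flight_time_fraction(-5), ">= 0")
})

test_that("routes export as GeoJSON LineStrings", {
  w <- ocean_world(spacing = 1, lat = c(50, 70), lon = c(-10, 10))
  r <- direct_route(c(-5, 55), c(5, 65), w, 9)
  path <- tempfile(fileext = ".geojson")
  write_route_geojson(r, path)
  gj <- jsonlite::read_json(path)
  geom <- gj$features[[1]]$geometry
  expect_identical(geom$type, "LineString")
  expect_length(geom$coordinates, nrow(r$waypoints))
  expect_equal(gj$features[[1]]$properties$total_km, r$total_km,
               tolerance = 1e-6)
})
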