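# Shared fixture builders: all synthetic, generated at test time.

# small circumpolar band world matching the demo conventions
demo_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config(1)
      cache <<- make_synthetic_world(
        grid = cfg$grid, members = cfg$members, warming = cfg$warming,
        seed = 1, winter_warm_sector = cfg$winter_warm_sector)
    }
    cache
  }
})

# single-member ocean-only world on a small fine grid
ocean_world <- function(seed = 1, spacing = 1, lat = c(50, 70),
                        lon = c(-10, 10)) {
  make_synthetic_world(grid = list(lat = lat, lon = lon, spacing = spacing),
                       members = "m1", warming = 2, seed = seed,
                       land_fun = function(lon, lat) rep(FALSE, length(lon)),
                       arctic_required = FALSE)
}

# world with a custom land pattern given as a function(lon, lat) -> logical
patterned_world <- function(land_fun, spacing = 1, lat = c(50, 70),
                            lon = c(-10, 10), seed = 1, warming = 2) {
  make_synthetic_world(grid = list(lat = lat, lon = lon, spacing = spacing),
                       members = "m1", warming = warming, seed = seed,
                       land_fun = land_fun, arctic_required = FALSE)
}

# overwrite one variable of a world with a constant (all months)
set_constant_field <- function(world, variable, value,
                               member = world$members[1],
                               scenario = "baseline") {
  f <- world$fields[[member]][[scenario]][[variable]]
  mask <- !is.na(f$values)
  f$values[mask] <- value
  world$fields[[member]][[scenario]][[variable]] <- f
  world
}

# brute-force optimal constrained path cost by DFS over simple paths
# (8-neighbour grid, land-run constraint, optional ice penalty)
brute_force_route_cost <- function(world, from_cell, to_cell, month,
                                   member = "m1", scenario = "baseline",
                                   land_limit = 100, beta = 0,
                                   ice_threshold = 0.5) {
  nlat <- length(world$lat); nlon <- length(world$lon)
  ice <- matrix(world$fields[[member]][[scenario]]$ice$values[month, , ],
                nlat, nlon)
  ice[is.na(ice)] <- 0
  land <- world$land
  best <- Inf
  visited <- matrix(FALSE, nlat, nlon)
  dfs <- function(i, j, run, cost) {
    if (cost >= best) return()
    if (i == to_cell[1] && j == to_cell[2]) { best <<- cost; return() }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nlat || j2 < 1 || j2 > nlon) next
      if (visited[i2, j2]) next
      len <- gc_distance(world$lon[j], world$lat[i],
                         world$lon[j2], world$lat[i2])
      land_leg <- (land[i, j] + land[i2, j2]) / 2 > 0.5
      run2 <- if (land_leg) run + len else 0
      if (run2 > land_limit) next
      leg_ice <- (ice[i, j] + ice[i2, j2]) / 2
      dfs(i2, j2, run2,
          cost + len * (1 + beta * (leg_ice >= ice_threshold)))
    }
    visited[i, j] <<- FALSE
  }
  dfs(from_cell[1], from_cell[2], 0, 0)
  best
}

# exhaustive-scan TSS oracle: evaluate sens + spec - 1 at a dense set of
# thresholds covering every possible split of the scores
brute_force_tss <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  u <- sort(unique(scores))
  cand <- sort(unique(c(u - 1e-9, u + 1e-9, (u[-1] + u[-length(u)]) / 2,
                        min(u) - 1, max(u) + 1)))
  best <- -Inf
  for (t in cand) {
    pred <- scores > t
    v <- sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0) - 1
    best <- max(best, v)
  }
  best
}
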