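#' Routing graph over the world grid
#'
#' Nodes are cell centers; edges connect 8-neighbours weighted by
#' great-circle length, annotated with land and sea-ice attributes taken as
#' the mean of the two endpoint cells for the given month.
#'
#' @param world a [make_synthetic_world()] result.
#' @param month month for the ice attribute.
#' @param member,scenario fields to read.
#' @return list with `nodes` and `edges` data frames.
#' @export
route_graph <- function(world, month, member = world$members[1],
                        scenario = "baseline") {
  nlat <- length(world$lat); nlon <- length(world$lon)
  if (nlat == 0L || nlon == 0L) stop("empty grid")
  ice <- matrix(world$fields[[member]][[scenario]]$ice$values[month, , ],
                nlat, nlon)
  ice[is.na(ice)] <- 0   # land cells carry no sea ice
  idx <- expand.grid(i = seq_len(nlat), j = seq_len(nlon))
  nodes <- data.frame(id = seq_len(nrow(idx)), i = idx$i, j = idx$j,
                      lon = world$lon[idx$j], lat = world$lat[idx$i],
                      land = world$land[cbind(idx$i, idx$j)],
                      ice = ice[cbind(idx$i, idx$j)])
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    i2 <- idx$i + offs$di[k]; j2 <- idx$j + offs$dj[k]
    ok <- i2 >= 1L & i2 <= nlat & j2 >= 1L & j2 <= nlon
    from <- nodes$id[ok]
    to <- (j2[ok] - 1L) * nlat + i2[ok]
    edges <- rbind(edges, data.frame(
      from = from, to = to,
      length_km = gc_distance(nodes$lon[from], nodes$lat[from],
                              nodes$lon[to], nodes$lat[to]),
      land = (nodes$land[from] + nodes$land[to]) / 2,
      ice = (nodes$ice[from] + nodes$ice[to]) / 2))
  }
  list(nodes = nodes, edges = edges)
}

route_obj <- function(waypoints, world, month, member, scenario,
                      strategy, ice_threshold = 0.5) {
  n <- nrow(waypoints)
  if (n < 2L) {
    return(structure(list(waypoints = waypoints,
                          legs = data.frame(length_km = numeric(),
                                            land = logical(),
                                            ice = numeric()),
                          total_km = 0, ice_km = 0, strategy = strategy,
                          month = month, feasible = TRUE),
                     class = "route"))
  }
  ice <- matrix(world$fields[[member]][[scenario]]$ice$values[month, , ],
                length(world$lat), length(world$lon))
  ice[is.na(ice)] <- 0
  cell_at <- function(lon, lat) {
    c(nearest_index(world$lat, lat), nearest_index(world$lon, lon))
  }
  legs <- data.frame(length_km = numeric(n - 1L), land = logical(n - 1L),
                     ice = numeric(n - 1L))
  for (k in seq_len(n - 1L)) {
    a <- cell_at(waypoints$lon[k], waypoints$lat[k])
    b <- cell_at(waypoints$lon[k + 1L], waypoints$lat[k + 1L])
    legs$length_km[k] <- gc_distance(waypoints$lon[k], waypoints$lat[k],
                                     waypoints$lon[k + 1L],
                                     waypoints$lat[k + 1L])
    legs$land[k] <- (world$land[a[1], a[2]] + world$land[b[1], b[2]]) / 2 > 0.5
    legs$ice[k] <- (ice[a[1], a[2]] + ice[b[1], b[2]]) / 2
  }
  structure(list(waypoints = waypoints, legs = legs,
                 total_km = sum(legs$length_km),
                 ice_km = sum(legs$length_km[legs$ice >= ice_threshold]),
                 strategy = strategy, month = month, feasible = TRUE),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %s: %.0f km (%d legs), %.0f km over dense ice, month %d\n",
              x$strategy, x$total_km, nrow(x$legs), x$ice_km, x$month))
  invisible(x)
}

# points along the great circle between two coordinates (inclusive)
gc_points <- function(lon1, lat1, lon2, lat2, n) {
  u <- unit_vectors(lon1, lat1)[1, ]; v <- unit_vectors(lon2, lat2)[1, ]
  omega <- acos(pmin(pmax(sum(u * v), -1), 1))
  t <- seq(0, 1, length.out = n)
  if (omega < 1e-12) {
    p <- matrix(rep(u, n), ncol = 3, byrow = TRUE)
  } else {
    p <- (sin((1 - t) * omega) %o% u + sin(t * omega) %o% v) / sin(omega)
  }
  data.frame(lon = atan2(p[, 2], p[, 1]) * 180 / pi,
             lat = asin(pmin(pmax(p[, 3], -1), 1)) * 180 / pi)
}

max_land_run <- function(legs) {
  run <- 0; worst <- 0
  for (k in seq_len(nrow(legs))) {
    run <- if (legs$land[k]) run + legs$length_km[k] else 0
    worst <- max(worst, run)
  }
  worst
}

#' Direct migratory route
#'
#' The great-circle line between colony and wintering location when it does
#' not require flying more than `land_limit` consecutive km across land;
#' otherwise the least-length 8-neighbour grid path subject to that
#' constraint (exact label-correcting search over states of node and
#' accumulated land-run, discretized in `bucket_km` steps).
#'
#' @param colony,destination `c(lon, lat)`.
#' @param world a [make_synthetic_world()] result.
#' @param month route month.
#' @param member,scenario fields to read.
#' @param land_limit maximum consecutive km across land (default 100).
#' @param bucket_km land-run discretization (default 10).
#' @return a `route` object (strategy `"direct"`).
#' @export
direct_route <- function(colony, destination, world, month,
                         member = world$members[1], scenario = "baseline",
                         land_limit = 100, bucket_km = 10) {
  gc_len <- gc_distance(colony[1], colony[2], destination[1], destination[2])
  npts <- max(2L, ceiling(gc_len / (KM_PER_DEG * min(world$spacing) / 2)) + 1L)
  wp <- gc_points(colony[1], colony[2], destination[1], destination[2], npts)
  cand <- route_obj(wp, world, month, member, scenario, "direct")
  if (max_land_run(cand$legs) <= land_limit) return(cand)
  constrained_route(colony, destination, world, month, member, scenario,
                    land_limit, bucket_km, beta = 0, ice_threshold = 0.5,
                    strategy = "direct")
}

#' Peripheral (ice-avoiding) migratory route
#'
#' Least-cost grid path with edge cost
#' `length * (1 + beta * [mean ice >= ice_threshold])` under the same
#' consecutive-land constraint as [direct_route()], i.e. a path minimizing
#' the distance flown over areas dense in sea ice.
#'
#' @inheritParams direct_route
#' @param ice_threshold sea-ice concentration defining "dense" ice.
#' @param beta penalty multiplier on ice-exposed length (default 10).
#' @return a `route` object (strategy `"peripheral"`).
#' @export
peripheral_route <- function(colony, destination, world, month,
                             member = world$members[1], scenario = "baseline",
                             land_limit = 100, bucket_km = 10,
                             ice_threshold = 0.5, beta = 10) {
  constrained_route(colony, destination, world, month, member, scenario,
                    land_limit, bucket_km, beta, ice_threshold, "peripheral")
}

# Dijkstra over (cell, land-run bucket) states; exact at the bucket
# resolution, with the bucket rounded up so accepted paths can never exceed
# the land limit.
constrained_route <- function(colony, destination, world, month, member,
                              scenario, land_limit, bucket_km, beta,
                              ice_threshold, strategy) {
  nlat <- length(world$lat); nlon <- length(world$lon)
  ncell <- nlat * nlon
  ice <- matrix(world$fields[[member]][[scenario]]$ice$values[month, , ],
                nlat, nlon)
  ice[is.na(ice)] <- 0
  land <- world$land
  nb <- as.integer(floor(land_limit / bucket_km)) + 1L
  nstate <- ncell * nb
  cell_id <- function(i, j) (j - 1L) * nlat + i
  si <- nearest_index(world$lat, colony[2])
  sj <- nearest_index(world$lon, colony[1])
  ti <- nearest_index(world$lat, destination[2])
  tj <- nearest_index(world$lon, destination[1])
  start <- cell_id(si, sj); target <- cell_id(ti, tj)

  dist <- rep(Inf, nstate); prev <- rep(NA_integer_, nstate)
  settled <- rep(FALSE, nstate)
  dist[start] <- 0   # bucket 0 (index offset 0)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  repeat {
    u <- which.min(ifelse(settled, Inf, dist))
    if (!is.finite(dist[u])) stop("no feasible path under the land constraint")
    settled[u] <- TRUE
    ucell <- (u - 1L) %% ncell + 1L
    if (ucell == target) break
    ub <- (u - 1L) %/% ncell
    ui <- (ucell - 1L) %% nlat + 1L
    uj <- (ucell - 1L) %/% nlat + 1L
    i2 <- ui + offs$di; j2 <- uj + offs$dj
    ok <- i2 >= 1L & i2 <= nlat & j2 >= 1L & j2 <= nlon
    i2 <- i2[ok]; j2 <- j2[ok]
    len <- gc_distance(world$lon[uj], world$lat[ui],
                       world$lon[j2], world$lat[i2])
    is_land_leg <- (land[cbind(ui, uj)] + land[cbind(i2, j2)]) / 2 > 0.5
    leg_ice <- (ice[ui, uj] + ice[cbind(i2, j2)]) / 2
    cost <- len * (1 + beta * (leg_ice >= ice_threshold))
    for (k in seq_along(i2)) {
      if (is_land_leg[k]) {
        run <- ub * bucket_km + len[k]
        if (run > land_limit) next
        b2 <- as.integer(ceiling(run / bucket_km - 1e-9))
        b2 <- min(b2, nb - 1L)
      } else {
        b2 <- 0L
      }
      v <- cell_id(i2[k], j2[k]) + ncell * b2
      alt <- dist[u] + cost[k]
      if (alt < dist[v] - 1e-12) {
        dist[v] <- alt
        prev[v] <- u
      }
    }
  }
  # reconstruct the settled target state
  ub_t <- which(settled[target + ncell * (seq_len(nb) - 1L)])
  v <- target + ncell * (ub_t[1] - 1L)
  cells <- integer()
  while (!is.na(v)) {
    cells <- c((v - 1L) %% ncell + 1L, cells)
    v <- prev[v]
  }
  if (cells[1] != start) cells <- c(start, cells)
  wi <- (cells - 1L) %% nlat + 1L
  wj <- (cells - 1L) %/% nlat + 1L
  wp <- data.frame(lon = world$lon[wj], lat = world$lat[wi])
  # keep the exact endpoints as route termini
  wp$lon[1] <- colony[1]; wp$lat[1] <- colony[2]
  wp$lon[nrow(wp)] <- destination[1]; wp$lat[nrow(wp)] <- destination[2]
  route_obj(wp, world, month, member, scenario, strategy, ice_threshold)
}

#' Length-weighted environmental averages along a route
#'
#' Samples each requested variable at leg midpoints (nearest cell) and
#' averages weighted by leg length; legs where a variable is undefined are
#' excluded from that variable's average.
#'
#' @param route a `route` object.
#' @param world a [make_synthetic_world()] result.
#' @param month month to read.
#' @param member,scenario fields to read.
#' @param variables variables to average.
#' @return named numeric vector.
#' @export
route_env_average <- function(route, world, month,
                              member = world$members[1],
                              scenario = "baseline",
                              variables = c("airtemp", "sst")) {
  wp <- route$waypoints
  year <- world$years[[scenario]]
  if (nrow(wp) < 2L) {
    return(extract_env(world, wp$lon[1], wp$lat[1], year, month, variables,
                       member))
  }
  mids <- t(vapply(seq_len(nrow(wp) - 1L), function(k) {
    p <- gc_points(wp$lon[k], wp$lat[k], wp$lon[k + 1L], wp$lat[k + 1L], 3L)
    c(p$lon[2], p$lat[2])
  }, numeric(2)))
  w <- route$legs$length_km
  out <- stats::setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    vals <- vapply(seq_len(nrow(mids)), function(k) {
      extract_env(world, mids[k, 1], mids[k, 2], year, month, v, member)[[v]]
    }, numeric(1))
    ok <- !is.na(vals) & w > 0
    if (!any(ok)) stop("variable '", v, "' missing along the entire route")
    out[[v]] <- sum(vals[ok] * w[ok]) / sum(w[ok])
  }
  out
}

#' Daily flight-time fraction of a one-month migration
#'
#' Fraction of each day spent flying when the route is spread evenly over
#' the migration window at constant air speed.
#'
#' @param length_km route length in km.
#' @param speed_ms flight speed in m/s (default 13).
#' @param duration_days migration duration in days (default 30).
#' @return fraction of each day in flight, in `[0, 1]`.
#' @export
flight_time_fraction <- function(length_km, speed_ms = 13,
                                 duration_days = 30) {
  if (length_km < 0) stop("length must be >= 0")
  f <- (length_km * 1000 / speed_ms) / (duration_days * 86400)
  if (f > 1) stop(sprintf("infeasible migration: flight fraction %.2f > 1", f))
  f
}

#' Export a route as a GeoJSON LineString
#'
#' @param route a `route` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_route_geojson <- function(route, path) {
  coords <- lapply(seq_len(nrow(route$waypoints)), function(k) {
    c(route$waypoints$lon[k], route$waypoints$lat[k])
  })
  feat <- list(type = "Feature",
               properties = list(strategy = route$strategy,
                                 month = route$month,
                                 total_km = route$total_km,
                                 ice_km = route$ice_km),
               geometry = list(type = "LineString", coordinates = coords))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
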