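#' Synthetic gridded polar world
#'
#' Generates monthly environmental fields emulating the gridded data sources
#' a hind-/forecast seabird analysis runs on: air temperature with a
#' latitudinal gradient, a seasonal cycle and a per-member warming trend;
#' sea-surface temperature, sea-ice concentration and snow-cover fraction
#' coupled to temperature; a land mask with a derived coast-distance class
#' raster; and a bathymetry-slope raster. One set of fields is produced per
#' climate member and per scenario (`"baseline"`, `"future"`), deterministic
#' for a given seed.
#'
#' @param grid list with `lat = c(min, max)`, `lon = c(min, max)` and
#'   `spacing` (degrees); cell-center registered.
#' @param members character vector of climate-member identifiers.
#' @param warming named numeric, future-scenario warming (degC) per member
#'   (recycled if unnamed scalar).
#' @param seed integer RNG seed.
#' @param land_fun `function(lon, lat)` returning `TRUE` for land; defaults
#'   to two meridional continents separating an "Atlantic" and a "Pacific"
#'   sector under an open Arctic basin.
#' @param winter_warm_sector optional sector anomaly
#'   `list(lon = c(min, max), months = int vector, delta = degC)`, or an
#'   unnamed list of several such sectors, adding sector-limited warm
#'   anomalies (used to construct contrasting ocean basins and warm inflow
#'   tongues).
#' @param years named integer vector, representative year per scenario.
#' @param arctic_required require the grid to reach north of 66.5 degrees
#'   (the analysis precondition); disable for regional test sub-grids.
#' @return an object of class `world_fields`.
#' @export
make_synthetic_world <- function(grid = list(lat = c(40, 90), lon = c(-180, 180),
                                             spacing = 2.5),
                                 members = c("m1", "m2"),
                                 warming = 3,
                                 seed = 1L,
                                 land_fun = NULL,
                                 winter_warm_sector = NULL,
                                 years = c(baseline = 2010L, future = 2055L),
                                 arctic_required = TRUE) {
  if (length(members) == 0L) stop("empty member list")
  sp <- rep(grid$spacing, length.out = 2L)  # c(lat, lon) spacing
  if (any(sp <= 0)) stop("grid spacing must be positive")
  if (is.null(names(warming))) {
    warming <- stats::setNames(rep_len(warming, length(members)), members)
  }
  lat <- seq(grid$lat[1] + sp[1] / 2, grid$lat[2] - sp[1] / 2 + 1e-9,
             by = sp[1])
  lon <- seq(grid$lon[1] + sp[2] / 2, grid$lon[2] - sp[2] / 2 + 1e-9,
             by = sp[2])
  if (length(lat) < 2L || length(lon) < 2L) stop("grid too small")
  if (arctic_required && max(lat) < 66.5) {
    stop("grid must include an Arctic zone (lat > 66.5); ",
         "use arctic_required = FALSE for regional sub-grids")
  }
  if (is.null(land_fun)) land_fun <- default_land_fun
  if (!is.null(winter_warm_sector) && !is.null(winter_warm_sector$lon)) {
    winter_warm_sector <- list(winter_warm_sector)
  }
  land <- outer(lat, lon, function(la, lo) land_fun(lo, la)) * 1L
  storage.mode(land) <- "integer"

  set.seed(as.integer(seed))
  slope <- synth_slope(lat, lon, land)
  coast <- coast_class(lat, lon, land)

  scen <- names(years)
  fields <- list()
  for (m in members) {
    fields[[m]] <- list()
    for (s in scen) {
      delta <- if (s == "future") warming[[m]] else 0
      fields[[m]][[s]] <- synth_member_fields(
        lat, lon, land, years[[s]], s, m, delta, winter_warm_sector)
    }
  }
  structure(
    list(lat = lat, lon = lon, spacing = sp, land = land, slope = slope,
         coast_class = coast, members = members, scenarios = scen,
         years = years, warming = warming, fields = fields,
         seed = as.integer(seed)),
    class = "world_fields")
}

# Two continents flanking an Atlantic (lon -60..10) and a Pacific
# (lon 140..180 and -180..-140) open sector, with an open Arctic basin.
default_land_fun <- function(lon, lat) {
  america <- lon >= -140 & lon <= -60 & lat < 72
  eurasia <- lon >= 10 & lon <= 140 & lat < 76
  america | eurasia
}

# smooth random surface: coarse white noise interpolated bilinearly
smooth_noise <- function(lat, lon, sd = 1, knots = 8L) {
  kla <- seq(min(lat), max(lat), length.out = knots)
  klo <- seq(min(lon), max(lon), length.out = knots)
  z <- matrix(stats::rnorm(knots * knots, sd = sd), knots, knots)
  ila <- interp_index(kla, lat); ilo <- interp_index(klo, lon)
  outer(1 - ila$w, 1 - ilo$w) * z[ila$i0, ilo$i0] +
    outer(1 - ila$w, ilo$w) * z[ila$i0, ilo$i1] +
    outer(ila$w, 1 - ilo$w) * z[ila$i1, ilo$i0] +
    outer(ila$w, ilo$w) * z[ila$i1, ilo$i1]
}

synth_slope <- function(lat, lon, land) {
  depth <- 2000 + 1500 * smooth_noise(lat, lon, sd = 1)
  dlat <- KM_PER_DEG * (lat[2] - lat[1])
  dlon <- outer(cos(lat * pi / 180), rep(KM_PER_DEG * (lon[2] - lon[1]),
                                         length(lon)))
  gy <- depth * 0; gx <- depth * 0
  gy[2:(nrow(depth) - 1), ] <- (depth[3:nrow(depth), ] -
                                  depth[1:(nrow(depth) - 2), ]) / (2 * dlat)
  gx[, 2:(ncol(depth) - 1)] <- (depth[, 3:ncol(depth)] -
                                  depth[, 1:(ncol(depth) - 2)]) /
    (2 * dlon[, 2:(ncol(depth) - 1)])
  sl <- atan(sqrt(gx^2 + gy^2) / 1000) * 180 / pi  # degrees of slope
  sl[land == 1L] <- NA_real_
  sl
}

#' Coast-distance classes from a land mask
#'
#' Classifies every marine cell by great-circle distance from its center to
#' the nearest coastal land-cell center, using right-open breakpoints
#' (default `{10, 20, 50, 100, 200}` km): code 1 is `< 10 km`, ..., code 6 is
#' `>= 200 km`.
#'
#' @param lat,lon axis coordinates.
#' @param land integer land mask `[lat, lon]`.
#' @param breaks class breakpoints in km.
#' @return integer matrix of class codes, `NA` over land.
#' @export
coast_class <- function(lat, lon, land, breaks = c(10, 20, 50, 100, 200)) {
  nlat <- length(lat); nlon <- length(lon)
  out <- matrix(NA_integer_, nlat, nlon)
  marine <- which(land == 0L, arr.ind = TRUE)
  if (nrow(marine) == 0L) return(out)
  coastal <- coastal_cells(land)
  if (nrow(coastal) == 0L) {           # no land: farthest class everywhere
    out[marine] <- length(breaks) + 1L
    return(out)
  }
  u <- unit_vectors(lon[marine[, 2]], lat[marine[, 1]])
  v <- unit_vectors(lon[coastal[, 2]], lat[coastal[, 1]])
  dmin <- rep(Inf, nrow(u))
  step <- 2000L  # chunk the dot-product matrix
  for (i0 in seq(1L, nrow(v), by = step)) {
    i1 <- min(i0 + step - 1L, nrow(v))
    cosd <- u %*% t(v[i0:i1, , drop = FALSE])
    cosd <- pmin(pmax(cosd, -1), 1)
    dmin <- pmin(dmin, 6371.0 * acos(apply(cosd, 1L, max)))
  }
  out[marine] <- findInterval(dmin, breaks) + 1L
  out
}

coastal_cells <- function(land) {
  nlat <- nrow(land); nlon <- ncol(land)
  pad <- matrix(1L, nlat + 2L, nlon + 2L)
  pad[2:(nlat + 1L), 2:(nlon + 1L)] <- land
  sea_nb <- matrix(FALSE, nlat, nlon)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    sea_nb <- sea_nb | (pad[(2:(nlat + 1L)) + di, (2:(nlon + 1L)) + dj] == 0L)
  }
  which(land == 1L & sea_nb, arr.ind = TRUE)
}

unit_vectors <- function(lon, lat) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

synth_member_fields <- function(lat, lon, land, year, scenario, member,
                                delta, warm_sector) {
  nlat <- length(lat); nlon <- length(lon)
  months <- 1:12
  time <- data.frame(year = rep.int(year, 12L), month = months)
  base <- outer(30 - 0.55 * lat, rep(1, nlon))        # latitudinal gradient
  amp <- outer(3 + 0.22 * lat, rep(1, nlon))          # seasonal amplitude
  amp <- amp * ifelse(land == 1L, 1, 0.5)             # maritime moderation
  spatial <- smooth_noise(lat, lon, sd = 1.0)         # per member+scenario
  at <- array(NA_real_, c(12L, nlat, nlon))
  for (m in months) {
    seas <- cos(2 * pi * (m - 7) / 12)
    sl <- base + amp * seas + delta + spatial +
      matrix(stats::rnorm(nlat * nlon, sd = 0.3), nlat, nlon)
    for (ws in warm_sector) {
      if (!m %in% ws$months) next
      in_lon <- lon >= ws$lon[1] & lon <= ws$lon[2]
      in_lat <- if (is.null(ws$lat)) rep(TRUE, nlat) else
        lat >= ws$lat[1] & lat <= ws$lat[2]
      sl[in_lat, in_lon] <- sl[in_lat, in_lon] + ws$delta
    }
    at[m, , ] <- sl
  }
  sst <- at; ice <- at
  for (m in months) {
    s <- 0.85 * at[m, , ] + 1.5               # pre-freezing-point SST scale
    s[land == 1L] <- NA_real_
    sst[m, , ] <- pmax(s, -1.8)
    # decreasing logistic of SST, evaluated before the freezing-point floor
    # so that additional warming keeps thinning ice over cold water;
    # center/scale chosen so water warmer than 5 degC is essentially ice-free
    ice[m, , ] <- stats::plogis(-(s + 2) / 1.5)
  }
  snow <- stats::plogis(-at / 2.0)           # decreasing logistic in airtemp
  for (m in months) {
    sn <- snow[m, , ]; sn[land == 0L] <- NA_real_; snow[m, , ] <- sn
  }
  gf <- function(v, vals, un) grid_field(v, un, lat, lon, time, vals,
                                         member = member, scenario = scenario)
  list(airtemp = gf("airtemp", at, "degC"),
       sst = gf("sst", sst, "degC"),
       ice = gf("ice", ice, "fraction"),
       snow = gf("snow", snow, "fraction"))
}

#' @export
print.world_fields <- function(x, ...) {
  cat(sprintf("<world_fields> %d x %d grid (%.3g x %.3g deg), %d members, scenarios: %s\n",
              length(x$lat), length(x$lon), x$spacing[1], x$spacing[2],
              length(x$members), paste(x$scenarios, collapse = ", ")))
  cat(sprintf("  land fraction %.2f; variables: airtemp, sst, ice, snow, slope, coast_class\n",
              mean(x$land)))
  invisible(x)
}

world_scenario_for_year <- function(world, year) {
  s <- names(world$years)[world$years == year]
  if (length(s) != 1L) stop("no scenario with representative year ", year)
  s
}

#' Extract environmental values at a point and date
#'
#' Nearest-cell lookup of the requested variables for the given location and
#' (year, month); the scenario is resolved from the year. Variables that are
#' undefined on the underlying surface (e.g. `sst` over land) are returned as
#' `NA`, never as zero.
#'
#' @param world a [make_synthetic_world()] result.
#' @param lon,lat point (degrees).
#' @param year,month date of the record.
#' @param variables character vector among `airtemp, sst, ice, snow, slope,
#'   coast_class, land`.
#' @param member climate member to read.
#' @return named numeric vector (one element per variable).
#' @export
extract_env <- function(world, lon, lat, year, month,
                        variables = c("airtemp", "sst", "ice", "snow",
                                      "slope", "coast_class"),
                        member = world$members[1]) {
  hla <- world$spacing[1] / 2; hlo <- world$spacing[2] / 2
  if (lat < world$lat[1] - hla || lat > world$lat[length(world$lat)] + hla ||
      lon < world$lon[1] - hlo || lon > world$lon[length(world$lon)] + hlo) {
    stop(sprintf("point (%.3f, %.3f) outside grid", lon, lat))
  }
  scen <- world_scenario_for_year(world, year)
  i <- nearest_index(world$lat, lat)
  j <- nearest_index(world$lon, lon)
  out <- stats::setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    out[[v]] <- switch(v,
      land = as.numeric(world$land[i, j]),
      slope = world$slope[i, j],
      coast_class = as.numeric(world$coast_class[i, j]),
      airtemp = , sst = , ice = , snow =
        world$fields[[member]][[scen]][[v]]$values[month, i, j],
      stop("unknown variable: ", v))
  }
  out
}

# environment matrix for a set of records (rows: records, cols: variables)
extract_env_records <- function(world, records, variables, member) {
  rows <- mapply(function(lon, lat, year, month) {
    extract_env(world, lon, lat, year, month, variables, member)
  }, records$lon, records$lat, records$year, records$month,
  SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  colnames(out) <- variables
  out
}

#' Mean of a field over the Arctic zone
#'
#' @param field a [grid_field].
#' @param lat_min southern limit of the zone (degrees north).
#' @param months months to include (default all).
#' @return mean value (missing cells excluded).
#' @export
arctic_mean <- function(field, lat_min = 66.5, months = NULL) {
  sel <- field$lat > lat_min
  if (!any(sel)) stop("no cells north of ", lat_min)
  m <- if (is.null(months)) seq_len(nrow(field$time)) else
    which(field$time$month %in% months)
  mean(field$values[m, sel, , drop = FALSE], na.rm = TRUE)
}

#' Sample presence occurrences from a known suitability surface
#'
#' Draws presence records over marine cells with probability proportional to
#' a logistic suitability `plogis(b0 + sum(b_v * env_v))` evaluated per cell
#' and month, so that distribution-model recovery can be tested against a
#' known generating law.
#'
#' @param world a [make_synthetic_world()] result.
#' @param coefs named numeric: `intercept` plus one coefficient per
#'   environmental variable (e.g. `c(intercept = 0, airtemp = 0.5)`); a name
#'   with suffix `_sq` (e.g. `airtemp_sq`) contributes a quadratic term, so
#'   thermal-band (unimodal) preferences can be expressed.
#' @param n number of presence records.
#' @param months candidate months.
#' @param member,scenario which fields to sample from.
#' @param seed RNG seed.
#' @param invert if `TRUE`, sample proportional to `1 - suitability`.
#' @param uniform if `TRUE`, ignore suitability (uniform null).
#' @return data frame `lon, lat, year, month, source, role`.
#' @export
sample_occurrences <- function(world, coefs, n, months = 10:12,
                               member = world$members[1],
                               scenario = "baseline", seed = 1L,
                               invert = FALSE, uniform = FALSE) {
  set.seed(as.integer(seed))
  su <- suitability_truth(world, coefs, months, member, scenario)
  w <- su$suitability
  if (uniform) w <- rep(1, length(w)) else if (invert) w <- 1 - w
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  data.frame(lon = su$lon[idx], lat = su$lat[idx],
             year = su$year[idx], month = su$month[idx],
             source = "synthetic", role = "presence")
}

# flatten marine (cell, month) combos with their true suitability
suitability_truth <- function(world, coefs, months, member, scenario) {
  marine <- which(world$land == 0L, arr.ind = TRUE)
  vars <- setdiff(names(coefs), "intercept")
  out <- NULL
  year <- world$years[[scenario]]
  for (m in months) {
    eta <- rep(coefs[["intercept"]], nrow(marine))
    ok <- rep(TRUE, nrow(marine))
    for (v in vars) {
      sq <- grepl("_sq$", v)
      base_v <- sub("_sq$", "", v)
      vals <- if (base_v == "slope") world$slope[marine]
      else if (base_v == "coast_class") as.numeric(world$coast_class[marine])
      else world$fields[[member]][[scenario]][[base_v]]$values[
        cbind(m, marine[, 1], marine[, 2])]
      if (sq) vals <- vals^2
      ok <- ok & !is.na(vals)
      eta <- eta + coefs[[v]] * ifelse(is.na(vals), 0, vals)
    }
    out <- rbind(out, data.frame(
      lon = world$lon[marine[, 2]][ok], lat = world$lat[marine[, 1]][ok],
      year = year, month = m, suitability = stats::plogis(eta[ok])))
  }
  out
}
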