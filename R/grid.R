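#' Monthly gridded environmental field
#'
#' A `grid_field` holds one environmental variable on a regular
#' latitude-longitude grid with a monthly time axis, tagged with the climate
#' member and scenario it belongs to. Values are stored as a 3-d array
#' indexed `[time, lat, lon]`; `NA` marks cells where the variable is
#' undefined (e.g. sea-surface temperature over land).
#'
#' @param variable variable name (e.g. `"airtemp"`, `"sst"`, `"ice"`).
#' @param units unit string (`"degC"`, `"fraction"`, `"deg_slope"`, ...).
#' @param lat,lon cell-center coordinates, uniform and strictly ascending;
#'   longitudes in degrees east within `[-180, 180)`.
#' @param time data frame with integer columns `year` and `month`.
#' @param values numeric array of dim `c(nrow(time), length(lat), length(lon))`.
#' @param member climate-member identifier.
#' @param scenario `"baseline"` or `"future"`.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(variable, units, lat, lon, time, values,
                       member = "obs", scenario = "baseline") {
  stopifnot(is.character(variable), length(variable) == 1L)
  check_axis(lat, "lat")
  check_axis(lon, "lon")
  if (any(lon < -180 | lon >= 180)) {
    stop("longitudes must lie in [-180, 180)")
  }
  time <- as.data.frame(time)
  stopifnot(all(c("year", "month") %in% names(time)))
  values <- as.array(values)
  if (!identical(dim(values), c(nrow(time), length(lat), length(lon)))) {
    stop("values must have dim [time, lat, lon] = [",
         nrow(time), ", ", length(lat), ", ", length(lon), "]")
  }
  structure(
    list(variable = variable, units = units, lat = as.numeric(lat),
         lon = as.numeric(lon), time = time, values = values,
         member = member, scenario = scenario),
    class = "grid_field")
}

check_axis <- function(x, name) {
  if (length(x) < 1L) stop(name, " axis is empty")
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0)) stop(name, " axis must be strictly ascending")
    if (max(d) - min(d) > 1e-8 * max(abs(d))) {
      stop(name, " axis must have constant spacing")
    }
  }
  invisible(TRUE)
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s] member=%s scenario=%s\n",
              x$variable, x$units, x$member, x$scenario))
  cat(sprintf("  grid: %d lat x %d lon (%.3g deg), %d time steps\n",
              length(x$lat), length(x$lon), grid_spacing(x), nrow(x$time)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%.4g, %.4g], %.1f%% missing\n",
              rng[1], rng[2], 100 * mean(is.na(x$values))))
  invisible(x)
}

grid_spacing <- function(field) {
  if (length(field$lat) > 1L) diff(field$lat[1:2]) else diff(field$lon[1:2])
}

time_index <- function(field, year, month) {
  i <- which(field$time$year == year & field$time$month == month)
  if (length(i) != 1L) {
    stop(sprintf("time (%d, %d) not present in field '%s'",
                 year, month, field$variable))
  }
  i
}

#' Bilinear regridding of a field to a finer grid
#'
#' Interpolates a [grid_field] bilinearly onto a regular target grid covering
#' the same extent. Output values are convex combinations of the four
#' surrounding source nodes, so they are bounded by the local source extrema;
#' any `NA` in the four-node stencil propagates to the target cell.
#'
#' @param field a [grid_field].
#' @param target_spacing target grid spacing in degrees; must not exceed the
#'   source spacing.
#' @return a [grid_field] on the refined grid.
#' @export
regrid_linear <- function(field, target_spacing) {
  stopifnot(inherits(field, "grid_field"))
  src <- grid_spacing(field)
  if (target_spacing <= 0) stop("target spacing must be positive")
  if (target_spacing > src + 1e-12) {
    stop("target spacing must be <= source spacing")
  }
  if (length(field$lat) < 2L || length(field$lon) < 2L) {
    stop("source grid needs >= 2 nodes per axis")
  }
  tlat <- seq(field$lat[1], field$lat[length(field$lat)], by = target_spacing)
  tlon <- seq(field$lon[1], field$lon[length(field$lon)], by = target_spacing)
  ilat <- interp_index(field$lat, tlat)
  ilon <- interp_index(field$lon, tlon)
  nt <- nrow(field$time)
  out <- array(NA_real_, dim = c(nt, length(tlat), length(tlon)))
  # weights for the 4-corner stencil, outer product per target cell
  for (t in seq_len(nt)) {
    sl <- field$values[t, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, length(field$lat), length(field$lon))
    v00 <- sl[ilat$i0, ilon$i0, drop = FALSE]
    v01 <- sl[ilat$i0, ilon$i1, drop = FALSE]
    v10 <- sl[ilat$i1, ilon$i0, drop = FALSE]
    v11 <- sl[ilat$i1, ilon$i1, drop = FALSE]
    wl <- ilat$w; wr <- ilon$w
    out[t, , ] <- outer(1 - wl, 1 - wr) * v00 + outer(1 - wl, wr) * v01 +
      outer(wl, 1 - wr) * v10 + outer(wl, wr) * v11
  }
  grid_field(field$variable, field$units, tlat, tlon, field$time, out,
             member = field$member, scenario = field$scenario)
}

# For each target coordinate return bracketing source indices and the
# fractional weight of the upper node.
interp_index <- function(src, tgt) {
  i0 <- findInterval(tgt, src, rightmost.closed = TRUE)
  i0 <- pmin(pmax(i0, 1L), length(src) - 1L)
  i1 <- i0 + 1L
  w <- (tgt - src[i0]) / (src[i1] - src[i0])
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0, i1 = i1, w = w)
}

nearest_index <- function(axis, x) {
  # ties (exact midpoints) resolve to the lower index: which.min returns the
  # first minimum and the axis is ascending
  which.min(abs(axis - x))
}

#' Nearest-cell lookup of a field value
#'
#' @param field a [grid_field].
#' @param lon,lat query point (degrees).
#' @param year,month time step to read.
#' @return the stored cell value (`NA` if the variable is undefined there).
#' @export
field_value_at <- function(field, lon, lat, year, month) {
  if (lat < field$lat[1] - grid_spacing(field) / 2 ||
      lat > field$lat[length(field$lat)] + grid_spacing(field) / 2 ||
      lon < field$lon[1] - grid_spacing(field) / 2 ||
      lon > field$lon[length(field$lon)] + grid_spacing(field) / 2) {
    stop(sprintf("point (%.3f, %.3f) outside grid", lon, lat))
  }
  ti <- time_index(field, year, month)
  field$values[ti, nearest_index(field$lat, lat), nearest_index(field$lon, lon)]
}

#' Write gridded fields to a CF-style NetCDF file
#'
#' Each field becomes one float variable on shared `lat`/`lon`/`time`
#' dimensions with `member` and `scenario` stored as variable attributes.
#' Byte-valued rasters (land mask, coast-distance class) may be included as
#' integer variables via `byte_layers`.
#'
#' @param fields named list of [grid_field]s sharing one grid and time axis.
#' @param path output file path.
#' @param byte_layers optional named list of integer matrices `[lat, lon]`.
#' @return `path`, invisibly.
#' @export
write_grid_nc <- function(fields, path, byte_layers = NULL) {
  stopifnot(length(fields) > 0L)
  f1 <- fields[[1]]
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", f1$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", f1$lon)
  dtim <- ncdf4::ncdim_def("time", "months since 0000-01",
                           f1$time$year * 12 + (f1$time$month - 1))
  vars <- lapply(names(fields), function(nm) {
    ncdf4::ncvar_def(nm, fields[[nm]]$units, list(dlon, dlat, dtim),
                     missval = -9999, prec = "float")
  })
  names(vars) <- names(fields)
  bvars <- list()
  if (!is.null(byte_layers)) {
    bvars <- lapply(names(byte_layers), function(nm) {
      ncdf4::ncvar_def(nm, "1", list(dlon, dlat), missval = -1L,
                       prec = "byte")
    })
    names(bvars) <- names(byte_layers)
  }
  nc <- ncdf4::nc_create(path, c(vars, bvars))
  on.exit(ncdf4::nc_close(nc))
  for (nm in names(fields)) {
    # [time, lat, lon] -> [lon, lat, time]
    ncdf4::ncvar_put(nc, vars[[nm]], aperm(fields[[nm]]$values, c(3, 2, 1)))
    ncdf4::ncatt_put(nc, nm, "member", fields[[nm]]$member)
    ncdf4::ncatt_put(nc, nm, "scenario", fields[[nm]]$scenario)
  }
  for (nm in names(bvars)) {
    ncdf4::ncvar_put(nc, bvars[[nm]], t(byte_layers[[nm]]))
  }
  invisible(path)
}

#' Read gridded fields written by [write_grid_nc()]
#'
#' @param path NetCDF file path.
#' @return list with elements `fields` (named list of [grid_field]s) and
#'   `byte_layers` (named list of integer matrices).
#' @export
read_grid_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  tv <- as.integer(round(nc$dim$time$vals))
  time <- data.frame(year = tv %/% 12L, month = tv %% 12L + 1L)
  fields <- list(); byte_layers <- list()
  for (nm in names(nc$var)) {
    v <- nc$var[[nm]]
    vals <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    if (v$ndims == 3L) {
      arr <- aperm(vals, c(3, 2, 1))
      att <- ncdf4::ncatt_get(nc, nm)
      fields[[nm]] <- grid_field(
        nm, v$units, lat, lon, time, arr,
        member = if (isTRUE(att$hasatt) || !is.null(att$member)) att$member else "obs",
        scenario = if (!is.null(att$scenario)) att$scenario else "baseline")
    } else {
      byte_layers[[nm]] <- t(matrix(vals, length(lon), length(lat)))
    }
  }
  list(fields = fields, byte_layers = byte_layers)
}
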