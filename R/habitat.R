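#' Binary habitat mask from a suitability map
#'
#' A cell is suitable when its habitat suitability index is strictly greater
#' than the threshold (default 0.9, a conservative cut).
#'
#' @param map a [ensemble_predict()] result (values in `[0, 1]`).
#' @param theta suitability threshold in `[0, 1]`.
#' @param context mask context tag (`"nesting"`, `"foraging"`,
#'   `"wintering"`, ...).
#' @return an object of class `habitat_mask` (logical matrix `[lat, lon]`,
#'   `NA` cells count as unsuitable).
#' @export
threshold_suitable <- function(map, theta = 0.9, context = "wintering") {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  mask <- !is.na(map$values) & map$values > theta
  habitat_mask(map$lat, map$lon, mask, context, map$member, map$months)
}

habitat_mask <- function(lat, lon, mask, context, member = "obs",
                         period = NULL) {
  structure(list(lat = lat, lon = lon, mask = mask, context = context,
                 member = member, period = period),
            class = "habitat_mask")
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat(sprintf("<habitat_mask> %s member=%s: %d of %d cells\n", x$context,
              x$member, sum(x$mask), length(x$mask)))
  invisible(x)
}

mask_cells <- function(mask) {
  ij <- which(mask$mask, arr.ind = TRUE)
  data.frame(lon = mask$lon[ij[, 2]], lat = mask$lat[ij[, 1]],
             i = ij[, 1], j = ij[, 2])
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon))) {
    stop("grid mismatch between masks")
  }
}

# TRUE for each row of `from` having >= 1 cell of `to` within `radius` km
# (cell-center great-circle distance, inclusive). A latitude-band prefilter
# keeps the candidate set small; results equal the brute-force all-pairs
# answer because a band of radius/KM_PER_DEG degrees contains every cell
# whose great-circle distance can be <= radius.
within_radius <- function(from, to, radius) {
  if (nrow(to) == 0L) return(rep(FALSE, nrow(from)))
  band <- radius / KM_PER_DEG + 1e-9
  vapply(seq_len(nrow(from)), function(k) {
    cand <- which(abs(to$lat - from$lat[k]) <= band)
    if (!length(cand)) return(FALSE)
    any(gc_distance(from$lon[k], from$lat[k],
                    to$lon[cand], to$lat[cand]) <= radius)
  }, logical(1))
}

#' Breeding areas: nesting sites near suitable foraging
#'
#' Retains suitable nesting cells that have at least one suitable foraging
#' cell within the foraging radius (default 200 km, the species' maximum
#' foraging range while provisioning), measured between cell centers.
#'
#' @param nesting,foraging [habitat_mask]s on the same grid.
#' @param radius foraging radius in km.
#' @return a `habitat_mask` with context `"breeding_area"`.
#' @export
breeding_sites <- function(nesting, foraging, radius = 200) {
  check_same_grid(nesting, foraging)
  nest <- mask_cells(nesting)
  keep <- within_radius(nest, mask_cells(foraging), radius)
  out <- matrix(FALSE, nrow(nesting$mask), ncol(nesting$mask))
  out[cbind(nest$i[keep], nest$j[keep])] <- TRUE
  habitat_mask(nesting$lat, nesting$lon, out, "breeding_area",
               nesting$member, nesting$period)
}

#' Residency areas: suitable wintering water near breeding sites
#'
#' Marine cells suitable for wintering that lie within the residency radius
#' (default 250 km) of any breeding cell. An empty result is a valid
#' "residency infeasible" outcome, not an error.
#'
#' @param breeding breeding-area [habitat_mask] (must be non-empty).
#' @param wintering marine suitable-wintering [habitat_mask], same grid.
#' @param radius residency radius in km.
#' @return a `habitat_mask` with context `"residency_area"`.
#' @export
residency_area <- function(breeding, wintering, radius = 250) {
  check_same_grid(breeding, wintering)
  if (!any(breeding$mask)) stop("breeding mask is empty")
  win <- mask_cells(wintering)
  keep <- within_radius(win, mask_cells(breeding), radius)
  out <- matrix(FALSE, nrow(wintering$mask), ncol(wintering$mask))
  out[cbind(win$i[keep], win$j[keep])] <- TRUE
  habitat_mask(wintering$lat, wintering$lon, out, "residency_area",
               wintering$member, wintering$period)
}

#' Spherical centroid of a habitat mask
#'
#' Mean of the cells' unit vectors (optionally weighted), re-normalized to
#' the sphere. If a land mask is supplied and the centroid falls on land, it
#' is snapped to the nearest cell of the input mask.
#'
#' @param mask a [habitat_mask] (non-empty).
#' @param weights optional per-cell weights (matrix conformable with the
#'   mask).
#' @param land optional integer land matrix used for the snap rule.
#' @return named numeric `c(lon, lat)`.
#' @export
wintering_centroid <- function(mask, weights = NULL, land = NULL) {
  cells <- mask_cells(mask)
  if (nrow(cells) == 0L) stop("empty mask")
  w <- if (is.null(weights)) rep(1, nrow(cells)) else
    weights[cbind(cells$i, cells$j)]
  u <- unit_vectors(cells$lon, cells$lat)
  v <- colSums(u * w) / sum(w)
  v <- v / sqrt(sum(v^2))
  lon <- atan2(v[2], v[1]) * 180 / pi
  lat <- asin(pmin(pmax(v[3], -1), 1)) * 180 / pi
  if (!is.null(land)) {
    i <- nearest_index(mask$lat, lat); j <- nearest_index(mask$lon, lon)
    if (land[i, j] == 1L) {
      d <- gc_distance(lon, lat, cells$lon, cells$lat)
      k <- which.min(d)
      lon <- cells$lon[k]; lat <- cells$lat[k]
    }
  }
  c(lon = as.numeric(lon), lat = as.numeric(lat))
}

#' Export a habitat mask as GeoJSON cell polygons
#'
#' Writes each masked cell as its grid-cell outline polygon (MultiPolygon
#' feature), a plain-text interchange form for mapping tools.
#'
#' @param mask a [habitat_mask].
#' @param path output path.
#' @param spacing cell size in degrees (default inferred from the axes).
#' @return `path`, invisibly.
#' @export
write_mask_geojson <- function(mask, path, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (length(mask$lat) > 1L) diff(mask$lat[1:2]) else
      diff(mask$lon[1:2])
  }
  cells <- mask_cells(mask)
  h <- spacing / 2
  polys <- lapply(seq_len(nrow(cells)), function(k) {
    lo <- cells$lon[k]; la <- cells$lat[k]
    # one polygon = list of rings; the outer ring is a closed point list
    list(list(c(lo - h, la - h), c(lo + h, la - h), c(lo + h, la + h),
              c(lo - h, la + h), c(lo - h, la - h)))
  })
  gj <- list(type = "Feature",
             properties = list(context = mask$context, member = mask$member),
             geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(gj)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
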