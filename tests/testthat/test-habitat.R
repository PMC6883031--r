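mk_map <- function(vals, lat, lon) {
  structure(list(lat = lat, lon = lon, values = vals, member = "m1",
                 scenario = "future", months = 1), class = "suitability_map")
}

mk_mask <- function(cells, lat, lon, context = "nesting") {
  m <- matrix(FALSE, length(lat), length(lon))
  if (nrow(cells)) m[cells] <- TRUE
  polarflyway:::habitat_mask(lat, lon, m, context)
}

test_that("suitability thresholding is strict and monotone in theta", {
  lat <- seq(50, 54, 2); lon <- seq(0, 4, 2)
  v <- matrix(c(0.9, 0.95, 0.5, NA, 0.91, 0.2, 1, 0, 0.89), 3, 3)
  m <- threshold_suitable(mk_map(v, lat, lon), 0.9)
  expect_false(m$mask[1, 1])            # exactly 0.9 is not "higher than"
  expect_true(m$mask[2, 2])
  expect_false(m$mask[1, 2])            # NA counts as unsuitable
  m0 <- threshold_suitable(mk_map(v, lat, lon), 0)
  expect_identical(sum(m0$mask), sum(!is.na(v) & v > 0))
  u <- mk_map(matrix(0.95, 3, 3), lat, lon)
  expect_identical(sum(threshold_suitable(u, 0.9)$mask), 9L)
  expect_error(threshold_suitable(u, 1.2), "\\[0, 1\\]")
  # decreasing theta can only grow the mask
  for (th in c(0.8, 0.5, 0.1)) {
    expect_true(all(m$mask <= threshold_suitable(mk_map(v, lat, lon),
                                                 th)$mask))
  }
})

test_that("breeding sites require foraging within the radius", {
  lat <- seq(50, 70, 0.5); lon <- seq(0, 10, 0.5)
  nest <- mk_mask(cbind(10, 5), lat, lon, "nesting")
  # adjacent foraging cell (~55 km at 0.5 deg) is retained
  close_f <- mk_mask(cbind(11, 5), lat, lon, "foraging")
  expect_true(any(breeding_sites(nest, close_f, 200)$mask))
  # nearest foraging 350 km away is dropped
  far_f <- mk_mask(cbind(10 + 7, 5), lat, lon, "foraging")  # 3.5 deg ~ 389 km
  expect_false(any(breeding_sites(nest, far_f, 200)$mask))
  # meridian-arc construction around the 200 km boundary:
  # 1.795 deg of latitude = 199.6 km (kept), 1.81 deg = 201.3 km (dropped)
  lat2 <- c(60, 60 + 1.795, 60 + 1.81); lon2 <- c(0, 1)
  nest2 <- mk_mask(cbind(1, 1), lat2, lon2, "nesting")
  expect_equal(gc_distance(0, 60, 0, 60 + 1.795), 199.6, tolerance = 1e-3)
  expect_equal(gc_distance(0, 60, 0, 60 + 1.81), 201.26, tolerance = 1e-2)
  kept <- breeding_sites(nest2, mk_mask(cbind(2, 1), lat2, lon2), 200)
  expect_true(any(kept$mask))
  dropped <- breeding_sites(nest2, mk_mask(cbind(3, 1), lat2, lon2), 200)
  expect_false(any(dropped$mask))
  expect_error(breeding_sites(nest, mk_mask(cbind(1, 1), lat2, lon2), 200),
               "grid mismatch")
})

test_that("banded neighbourhood search equals brute force and is monotone", {
  set.seed(23)
  lat <- seq(55, 75, 2.5); lon <- seq(-20, 20, 5)
  from <- cbind(sample(length(lat), 12, TRUE), sample(length(lon), 12, TRUE))
  to <- cbind(sample(length(lat), 8, TRUE), sample(length(lon), 8, TRUE))
  a <- mk_mask(unique(from), lat, lon)
  b <- mk_mask(unique(to), lat, lon)
  masks <- list()
  for (r in c(100, 250, 500, 1000)) {
    res <- breeding_sites(a, b, r)
    # brute force over all pairs
    fa <- polarflyway:::mask_cells(a); fb <- polarflyway:::mask_cells(b)
    brute <- vapply(seq_len(nrow(fa)), function(k) {
      any(gc_distance(fa$lon[k], fa$lat[k], fb$lon, fb$lat) <= r)
    }, logical(1))
    expect_identical(res$mask[cbind(fa$i, fa$j)], brute)
    masks[[as.character(r)]] <- res$mask
  }
  expect_true(all(masks[["100"]] <= masks[["250"]]))
  expect_true(all(masks[["250"]] <= masks[["500"]]))
})

test_that("residency areas follow the distance rule and may be empty", {
  lat <- seq(70, 80, 1); lon <- seq(0, 40, 2)
  breeding <- mk_mask(cbind(6, 5), lat, lon, "breeding_area")
  near <- mk_mask(cbind(6, 6), lat, lon, "wintering")   # ~60 km at 75N
  expect_true(any(residency_area(breeding, near, 250)$mask))
  far <- mk_mask(cbind(6, 15), lat, lon, "wintering")   # ~560 km away
  expect_false(any(residency_area(breeding, far, 250)$mask))
  # radius zero keeps only coincident cells
  self <- mk_mask(cbind(6, 5), lat, lon, "wintering")
  expect_identical(residency_area(breeding, self, 0)$mask, self$mask)
  expect_error(residency_area(mk_mask(matrix(0, 0, 2), lat, lon), near, 250),
               "empty")
})

test_that("spherical centroids match the unit-vector oracle and snap rule", {
  lat <- seq(50, 70, 2.5); lon <- seq(-20, 20, 2.5)
  single <- mk_mask(cbind(3, 4), lat, lon)
  expect_equal(unname(wintering_centroid(single)),
               c(lon[4], lat[3]), tolerance = 1e-9)
  # symmetry about a meridian
  j1 <- which(lon == -5); j2 <- which(lon == 5)
  sym <- mk_mask(rbind(c(4, j1), c(4, j2)), lat, lon)
  expect_equal(unname(wintering_centroid(sym)[1]), 0, tolerance = 1e-9)
  # explicit vector-mean oracle for cells at (0E, 60N) and (10E, 60N)
  lat2 <- seq(55, 65, 1); lon2 <- seq(-5, 15, 5)
  two <- mk_mask(rbind(c(6, 2), c(6, 4)), lat2, lon2)
  u <- polarflyway:::unit_vectors(c(0, 10), c(60, 60))
  v <- colMeans(u); v <- v / sqrt(sum(v^2))
  oracle <- c(atan2(v[2], v[1]), asin(v[3])) * 180 / pi
  got <- wintering_centroid(two)
  expect_equal(unname(got), oracle, tolerance = 1e-9)
  expect_equal(unname(got[1]), 5, tolerance = 1e-9)
  expect_gt(got[2], 60)          # great-circle midpoint bulges poleward
  # land snap: centroid on land moves to the nearest masked cell
  land <- matrix(0L, length(lat2), length(lon2)); land[6, 3] <- 1L
  snapped <- wintering_centroid(two, land = land)
  expect_true(unname(snapped[1]) %in% c(0, 10))
  expect_error(wintering_centroid(mk_mask(matrix(0, 0, 2), lat2, lon2)),
               "empty")
})

test_that("GeoJSON mask export writes valid polygons", {
  lat <- seq(50, 54, 2); lon <- seq(0, 4, 2)
  m <- mk_mask(rbind(c(1, 1), c(2, 2)), lat, lon, "wintering")
  path <- tempfile(fileext = ".geojson")
  write_mask_geojson(m, path)
  gj <- jsonlite::read_json(path)
  expect_identical(gj$type, "FeatureCollection")
  geom <- gj$features[[1]]$geometry
  expect_identical(geom$type, "MultiPolygon")
  expect_length(geom$coordinates, 2)
  ring <- geom$coordinates[[1]][[1]]
  expect_length(ring, 5)  # closed ring
})
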