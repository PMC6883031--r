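presences_at <- function(world, cells, months, year = 2010) {
  data.frame(lon = world$lon[cells[, 2]], lat = world$lat[cells[, 1]],
             year = year, month = months, source = "synthetic",
             role = "presence")
}

test_that("envelope pseudo-absences avoid the presence envelope", {
  w <- ocean_world(seed = 2, spacing = 2, lat = c(40, 70), lon = c(-20, 20))
  pres <- presences_at(w, rbind(c(2, 3), c(3, 5), c(4, 8), c(2, 9)),
                       months = c(1, 1, 2, 2))
  sets <- sample_pa_envelope(pres, w, "airtemp", n = 200, sets = 5,
                             seed = 10)
  expect_length(sets, 5)
  expect_true(all(vapply(sets, nrow, integer(1)) == 200))
  env <- polarflyway:::extract_env_records(w, pres, "airtemp", "m1")
  lo <- min(env); hi <- max(env)
  cand <- polarflyway:::candidate_cells(w, "airtemp", months = 1:2)
  for (s in sets) {
    vals <- cand$airtemp[match(paste(s$lon, s$lat),
                               paste(cand$lon, cand$lat))]
    expect_true(all(vals < lo | vals > hi))
  }
  # requesting more than the eligible pool without replacement fails
  pool <- sum(cand$airtemp < lo | cand$airtemp > hi)
  expect_error(sample_pa_envelope(pres, w, "airtemp", n = pool + 1, sets = 1,
                                  seed = 1, replace = FALSE),
               "without replacement")
  # with replacement the full count is honoured over <= pool distinct cells
  big <- sample_pa_envelope(pres, w, "airtemp", n = 1000, sets = 1,
                            seed = 1)[[1]]
  expect_identical(nrow(big), 1000L)
  expect_lte(nrow(unique(big[c("lon", "lat")])), pool)
})

test_that("envelope covering the whole domain is an explicit error", {
  w <- ocean_world(seed = 2, spacing = 2, lat = c(40, 70), lon = c(-20, 20))
  # single-month presences at the coldest and warmest January cells leave
  # no cell outside the envelope
  cand <- polarflyway:::candidate_cells(w, "airtemp", months = 1)
  iex <- c(which.min(cand$airtemp), which.max(cand$airtemp))
  pres <- data.frame(lon = cand$lon[iex], lat = cand$lat[iex],
                     year = 2010, month = 1)
  expect_error(sample_pa_envelope(pres, w, "airtemp", n = 10, sets = 1,
                                  seed = 1),
               "envelope covers the whole domain")
})

test_that("buffer pseudo-absences respect the angular exclusion", {
  w <- ocean_world(seed = 3, spacing = 1, lat = c(50, 70), lon = c(-8, 8))
  pres <- data.frame(lon = 0.5, lat = 55.5, year = 2010, month = 1)
  pres <- rbind(pres, pres)  # need >= 2 presences
  sets <- sample_pa_buffer(pres, w, "airtemp", n = 50, sets = 10,
                           buffer_deg = 2, seed = 5)
  expect_length(sets, 10)
  expect_identical(sum(vapply(sets, nrow, integer(1))), 500L)
  for (s in sets) {
    ang <- gc_distance(s$lon, s$lat, 0.5, 55.5) / (6371 * pi / 180)
    expect_true(all(ang > 2))
  }
  # spherical law of cosines oracle: 1 deg east + 1 deg north at the
  # equator is ~1.414 deg of arc, inside the buffer; 2.5 deg north is out
  d_in <- gc_distance(0.5, 0.5, 1.5, 1.5) / (6371 * pi / 180)
  rad <- pi / 180
  locos <- acos(sin(0.5 * rad) * sin(1.5 * rad) +
                  cos(0.5 * rad) * cos(1.5 * rad) * cos(1 * rad)) / rad
  expect_equal(d_in, locos, tolerance = 1e-9)
  expect_equal(gc_distance(0, 0, 1, 1) / (6371 * pi / 180),
               acos(cos(rad)^2) / rad, tolerance = 1e-9)  # ~1.414 deg
  expect_lt(d_in, 2)
  expect_gt(gc_distance(0.5, 0.5, 0.5, 3.0) / (6371 * pi / 180), 2)
})

test_that("time-stamping reuses the presence date distribution", {
  w <- ocean_world(seed = 4)
  pres <- presences_at(w, rbind(c(2, 2), c(3, 3)), months = c(1, 1))
  pa <- list(data.frame(lon = 0, lat = 55, role = "pseudo_absence"))
  out <- timestamp_pa(pa, pres, seed = 2)[[1]]
  expect_true(all(out$month == 1) && all(out$year == 2010))

  pres2 <- presences_at(w, matrix(rep(c(2, 2), 400), ncol = 2, byrow = TRUE),
                        months = rep(c(3, 9), each = 200))
  pa2 <- list(data.frame(lon = rep(0, 2000), lat = 55,
                         role = "pseudo_absence"))
  out2 <- timestamp_pa(pa2, pres2, seed = 2)[[1]]
  share <- mean(out2$month == 3)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(share - 0.5), 3 * se)
  out2b <- timestamp_pa(pa2, pres2, seed = 2)[[1]]
  expect_identical(out2, out2b)
})

test_that("TSS equals the exhaustive threshold scan", {
  expect_equal(tss(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$tss, 1)
  expect_equal(tss(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$tss, 0)
  ex <- tss(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(ex$tss, 0.5)
  expect_equal(ex$threshold, 0.25)  # tie broken by the lower threshold
  expect_error(tss(c(0.1, 0.9), c(1, 1)), "both classes")
  set.seed(13)
  for (k in 1:25) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)   # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(tss(scores, labels)$tss, brute_force_tss(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ensemble dimensions, determinism and importance ranking", {
  w <- demo_world()
  coefs <- c(intercept = 0.5, airtemp = 0.25, slope = -1.2)
  pres <- sample_occurrences(w, coefs, 120, months = c(11, 12, 1), seed = 6)
  pa <- sample_pa_buffer(pres, w, c("airtemp", "ice", "slope"), n = 120,
                         sets = 5, seed = 7)
  pa <- timestamp_pa(pa, pres, seed = 8)
  ens <- fit_ensemble(pres, pa, w, c("airtemp", "ice", "slope"), runs = 3,
                      seed = 9)
  expect_identical(length(ens$models), 4L * 5L * 3L)   # learners x sets x runs
  expect_true(all(vapply(ens$models, `[[`, numeric(1), "tss") >= -1))
  ens2 <- fit_ensemble(pres, pa, w, c("airtemp", "ice", "slope"), runs = 3,
                       seed = 9)
  expect_identical(vapply(ens$models, `[[`, numeric(1), "tss"),
                   vapply(ens2$models, `[[`, numeric(1), "tss"))
  imp <- ensemble_importance(ens)
  # the driver of the generating law outranks the zero-coefficient ice term
  expect_gt(imp[["airtemp"]], imp[["ice"]])
})

test_that("TSS-weighted prediction follows the stated formula and bounds", {
  mk <- function(p, w) {
    list(learner = "const", set = 1, run = 1, model = p,
         predict = function(model, x) rep(model, nrow(x)),
         tss = w, threshold = 0.5, importance = c(a = 0))
  }
  ens <- structure(list(models = list(mk(0.9, 0.2), mk(0.5, 0.6)),
                        variables = "a"), class = "fitted_ensemble")
  x <- data.frame(a = 1:3)
  expect_equal(predict_ensemble(ens, x), rep(0.6, 3))  # (0.18+0.30)/0.8
  # equal weights give the arithmetic mean
  ens$models <- list(mk(0.2, 0.5), mk(0.8, 0.5))
  expect_equal(predict_ensemble(ens, x), rep(0.5, 3))
  # zero-weight member has no effect
  ens$models <- list(mk(0.2, 0.5), mk(0.99, 0))
  expect_equal(predict_ensemble(ens, x), rep(0.2, 3))
  ens$models <- list(mk(0.2, 0), mk(0.99, -0.5))
  expect_error(predict_ensemble(ens, x), "weights")
  # map values stay within member prediction bounds
  w <- demo_world()
  coefs <- c(intercept = 0.5, airtemp = 0.25, slope = -1.2)
  pres <- sample_occurrences(w, coefs, 80, months = c(12, 1), seed = 16)
  pa <- timestamp_pa(sample_pa_buffer(pres, w, c("airtemp", "slope"),
                                      n = 80, sets = 2, seed = 17),
                     pres, seed = 18)
  fitted <- fit_ensemble(pres, pa, w, c("airtemp", "slope"), runs = 1,
                         seed = 19)
  x <- polarflyway:::month_features(w, c("airtemp", "slope"), 12, "m1",
                                    "baseline")
  ok <- stats::complete.cases(x)
  preds <- vapply(fitted$models, function(m) {
    m$predict(m$model, x[ok, , drop = FALSE])
  }, numeric(sum(ok)))
  comb <- predict_ensemble(fitted, x[ok, , drop = FALSE])
  expect_true(all(comb >= apply(preds, 1, min) - 1e-9))
  expect_true(all(comb <= apply(preds, 1, max) + 1e-9))
})

test_that("Boyce index responds to the presence sampling law", {
  # direct Monte-Carlo on a synthetic suitability surface
  set.seed(31)
  res <- replicate(8, {
    bg <- runif(4000)
    pres <- sample(bg, 400, prob = bg, replace = TRUE)
    unif <- sample(bg, 400, replace = TRUE)
    inv <- sample(bg, 400, prob = 1 - bg, replace = TRUE)
    c(pos = boyce_index(pres, bg), null = boyce_index(unif, bg),
      neg = boyce_index(inv, bg))
  })
  expect_gt(median(res["pos", ]), 0.8)
  expect_lt(abs(median(res["null", ])), 0.3)
  expect_lt(median(res["neg", ]), -0.8)
  expect_error(boyce_index(rep(0.5, 20), runif(100)), "identical")
  expect_error(boyce_index(runif(5), runif(100)), ">= 10")
})

test_that("cross-member CV maps follow the population formula", {
  mk_map <- function(vals) {
    structure(list(lat = 1:2, lon = 1:2, values = vals, member = "x",
                   scenario = "future", months = 1),
              class = "suitability_map")
  }
  a <- mk_map(matrix(c(0.4, 0, 0.3, NA), 2, 2))
  b <- mk_map(matrix(c(0.6, 0, 0.3, NA), 2, 2))
  cv <- cv_map(list(a, b))
  expect_equal(cv$values[1, 1], 0.1 / 0.5)   # SD 0.1 over mean 0.5
  expect_true(is.na(cv$values[2, 1]))        # zero mean is undefined
  expect_equal(cv$values[1, 2], 0)           # identical values
  expect_error(cv_map(list(a)), ">= 2")
  c_bad <- mk_map(matrix(0.5, 2, 2)); c_bad$lat <- 2:3
  expect_error(cv_map(list(a, c_bad)), "grid mismatch")
})
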