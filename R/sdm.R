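#' Candidate cells with complete environments
#'
#' Cells whose time-averaged values of every requested variable are defined;
#' used as the sampling universe for pseudo-absence designs.
#'
#' @param world a [make_synthetic_world()] result.
#' @param variables environmental variables required.
#' @param member,scenario which fields to read.
#' @param months months over which monthly variables are averaged (default
#'   all twelve); pass the season months so envelope tests compare
#'   like-for-like with seasonal presence environments.
#' @return data frame `lon, lat, i, j` plus one time-mean column per variable.
#' @keywords internal
candidate_cells <- function(world, variables, member = world$members[1],
                            scenario = "baseline", months = 1:12) {
  nlat <- length(world$lat); nlon <- length(world$lon)
  idx <- expand.grid(i = seq_len(nlat), j = seq_len(nlon))
  out <- data.frame(lon = world$lon[idx$j], lat = world$lat[idx$i],
                    i = idx$i, j = idx$j)
  for (v in variables) {
    vals <- switch(v,
      slope = world$slope[cbind(idx$i, idx$j)],
      coast_class = as.numeric(world$coast_class[cbind(idx$i, idx$j)]),
      land = as.numeric(world$land[cbind(idx$i, idx$j)]),
      apply(world$fields[[member]][[scenario]][[v]]$values[months, , ,
                                                           drop = FALSE],
            c(2, 3), mean)[cbind(idx$i, idx$j)])
    out[[v]] <- vals
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Environmental-envelope (SRE) pseudo-absence sets
#'
#' Computes the per-predictor min-max envelope of the presence environments
#' and samples pseudo-absences uniformly among candidate cells whose
#' (time-mean) environment lies outside the envelope in at least one
#' predictor — i.e. outside the species' current range in environmental
#' space.
#'
#' @param presences presence data frame (`lon, lat, year, month`).
#' @param world a [make_synthetic_world()] result.
#' @param variables predictors defining the envelope.
#' @param n records per set (default 1000).
#' @param sets number of independent sets (default 5).
#' @param seed RNG seed.
#' @param member,scenario fields to read.
#' @param replace sample cells with replacement (default `TRUE`); with
#'   `replace = FALSE` an error is raised when fewer eligible cells than `n`
#'   exist.
#' @return list of `sets` data frames (`lon, lat, role`).
#' @export
sample_pa_envelope <- function(presences, world, variables, n = 1000L,
                               sets = 5L, seed = 1L,
                               member = world$members[1],
                               scenario = "baseline", replace = TRUE) {
  if (nrow(presences) < 2L) stop("need >= 2 presences")
  env <- extract_env_records(world, presences, variables, member)
  env <- env[stats::complete.cases(env), , drop = FALSE]
  lo <- apply(env, 2, min); hi <- apply(env, 2, max)
  cand <- candidate_cells(world, variables, member, scenario,
                          months = sort(unique(presences$month)))
  outside <- rep(FALSE, nrow(cand))
  for (v in variables) {
    outside <- outside | cand[[v]] < lo[[v]] | cand[[v]] > hi[[v]]
  }
  if (!any(outside)) {
    stop("presence envelope covers the whole domain for predictors: ",
         paste(variables, collapse = ", "))
  }
  pool <- cand[outside, , drop = FALSE]
  if (!replace && nrow(pool) < n) {
    stop(sprintf("only %d eligible cells for %d pseudo-absences without replacement",
                 nrow(pool), n))
  }
  set.seed(as.integer(seed))
  lapply(seq_len(sets), function(s) {
    k <- sample.int(nrow(pool), n, replace = replace)
    data.frame(lon = pool$lon[k], lat = pool$lat[k], role = "pseudo_absence",
               set = s)
  })
}

#' Distance-buffer pseudo-absence sets
#'
#' Samples pseudo-absences uniformly among candidate cells whose angular
#' great-circle distance to every presence exceeds `buffer_deg` degrees of
#' arc.
#'
#' @inheritParams sample_pa_envelope
#' @param n records per set (default 100).
#' @param sets number of sets (default 10).
#' @param buffer_deg exclusion radius in degrees of arc (default 2).
#' @return list of `sets` data frames.
#' @export
sample_pa_buffer <- function(presences, world, variables, n = 100L,
                             sets = 10L, buffer_deg = 2, seed = 1L,
                             member = world$members[1], scenario = "baseline",
                             replace = TRUE) {
  if (nrow(presences) < 2L) stop("need >= 2 presences")
  cand <- candidate_cells(world, variables, member, scenario,
                          months = sort(unique(presences$month)))
  min_deg <- rep(Inf, nrow(cand))
  for (k in seq_len(nrow(presences))) {
    d <- gc_distance(cand$lon, cand$lat, presences$lon[k], presences$lat[k])
    min_deg <- pmin(min_deg, d / KM_PER_DEG)
  }
  pool <- cand[min_deg > buffer_deg, , drop = FALSE]
  if (nrow(pool) == 0L) stop("no cells outside the presence buffer")
  if (!replace && nrow(pool) < n) {
    stop("not enough eligible cells without replacement")
  }
  set.seed(as.integer(seed))
  lapply(seq_len(sets), function(s) {
    k <- sample.int(nrow(pool), n, replace = replace)
    data.frame(lon = pool$lon[k], lat = pool$lat[k], role = "pseudo_absence",
               set = s)
  })
}

#' Time-stamp pseudo-absences from the presence date distribution
#'
#' Draws `(year, month)` pairs with replacement from the empirical date
#' distribution of the presences and assigns them to each pseudo-absence
#' record, so pseudo-absence environments are extracted at their own
#' location and date.
#'
#' @param pa_sets list of pseudo-absence data frames.
#' @param presences dated presence data frame.
#' @param seed RNG seed.
#' @return the list of sets with `year` and `month` columns added.
#' @export
timestamp_pa <- function(pa_sets, presences, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(pa_sets, function(pa) {
    k <- sample.int(nrow(presences), nrow(pa), replace = TRUE)
    pa$year <- presences$year[k]
    pa$month <- presences$month[k]
    pa
  })
}

#' True Skill Statistic with optimal threshold
#'
#' `TSS(theta) = sensitivity(theta) + specificity(theta) - 1` with positives
#' predicted where `score > theta`. Candidate thresholds are the midpoints
#' of consecutive sorted unique scores; the maximum is returned, ties broken
#' by the lower threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) observed classes.
#' @return list with `tss` and `threshold`.
#' @export
tss <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) return(list(tss = 0, threshold = u[1]))
  # midpoints of sorted unique scores, plus all-positive / all-negative
  # extremes so the maximum can never fall below zero
  th <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  vals <- vapply(th, function(t) tss_at(scores, labels, t), numeric(1))
  best <- which(vals == max(vals))[1L]   # first = lowest threshold
  list(tss = vals[best], threshold = th[best])
}

tss_at <- function(scores, labels, threshold) {
  pred <- scores > threshold
  sens <- sum(pred & labels == 1L) / sum(labels == 1L)
  spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
  sens + spec - 1
}

#' Default learner set
#'
#' Four pluggable presence/pseudo-absence classifiers mirroring the usual
#' four-algorithm ensemble: a boosted-tree model (xgboost), a random forest
#' (ranger), a classification tree (rpart) and a linear discriminant
#' (MASS::lda). Each learner is a list with `id`,
#' `fit(x, y, seed, weights)` and `predict(model, x)` returning presence
#' probabilities. The case weights passed by [fit_ensemble()] give both
#' classes equal total weight (prevalence 0.5), so presence probabilities
#' are not shrunk by the presence/pseudo-absence imbalance.
#'
#' @return named list of learner specifications.
#' @export
default_learners <- function() {
  list(
    brt = list(
      id = "brt",
      fit = function(x, y, seed, weights) {
        xgboost::xgboost(as.matrix(x), factor(y, levels = c(0, 1)),
                         weights = weights,
                         nrounds = 60, max_depth = 3, learning_rate = 0.2,
                         nthreads = 1, verbosity = 0, seed = seed)
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, as.matrix(x), type = "response"))
      }),
    rf = list(
      id = "rf",
      fit = function(x, y, seed, weights) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 200,
                       case.weights = weights, num.threads = 1, seed = seed)
      },
      predict = function(model, x) {
        stats::predict(model, data = x, num.threads = 1)$predictions[, "1"]
      }),
    cta = list(
      id = "cta",
      fit = function(x, y, seed, weights) {
        d <- cbind(x, .y = factor(y, levels = c(0, 1)))
        w <- weights
        rpart::rpart(.y ~ ., data = d, method = "class", weights = w,
                     control = rpart::rpart.control(cp = 0.005, xval = 0))
      },
      predict = function(model, x) {
        stats::predict(model, newdata = x, type = "prob")[, "1"]
      }),
    fda = list(
      id = "fda",
      fit = function(x, y, seed, weights) {
        MASS::lda(x, grouping = factor(y), prior = c(0.5, 0.5))
      },
      predict = function(model, x) {
        stats::predict(model, newdata = x)$posterior[, "1"]
      })
  )
}

#' Fit a pseudo-absence ensemble
#'
#' Fits every learner on every pseudo-absence set for `runs` random
#' cross-validation repeats: each run holds out a random fraction
#' `1 - split` of the data, scores the model with [tss()] on the hold-out,
#' and computes permutation variable importance (one minus the correlation
#' between predictions on intact and permuted training features, averaged
#' over `n_perm` permutations).
#'
#' @param presences dated presence data frame.
#' @param pa_sets list of dated pseudo-absence sets (see [timestamp_pa()]).
#' @param world a [make_synthetic_world()] result.
#' @param variables predictor variables.
#' @param learners learner list (default [default_learners()]).
#' @param runs cross-validation repeats per set (default 3).
#' @param split training fraction (default 0.75).
#' @param seed RNG seed.
#' @param member,scenario fields to read.
#' @param n_perm permutations per importance estimate.
#' @return an object of class `fitted_ensemble`.
#' @export
fit_ensemble <- function(presences, pa_sets, world, variables,
                         learners = default_learners(), runs = 3L,
                         split = 0.75, seed = 1L,
                         member = world$members[1], scenario = "baseline",
                         n_perm = 3L) {
  pres_env <- model_frame(world, presences, variables, member, label = 1L)
  models <- list()
  counter <- 0L
  for (s in seq_along(pa_sets)) {
    pa_env <- model_frame(world, pa_sets[[s]], variables, member, label = 0L)
    dat <- rbind(pres_env, pa_env)
    x <- dat[variables]
    if (any(vapply(x, function(col) stats::sd(col) == 0, logical(1)))) {
      stop("degenerate (constant) feature in model frame")
    }
    y <- dat$.label
    for (r in seq_len(runs)) {
      for (ln in learners) {
        counter <- counter + 1L
        mseed <- (as.integer(seed) + 7919L * counter) %% 2147483647L
        set.seed(mseed)
        itrain <- sample.int(nrow(x), round(split * nrow(x)))
        if (length(unique(y[itrain])) < 2L ||
            length(unique(y[-itrain])) < 2L) next
        yt <- y[itrain]
        cw <- ifelse(yt == 1L, length(yt) / (2 * sum(yt == 1L)),
                     length(yt) / (2 * sum(yt == 0L)))
        fitted <- ln$fit(x[itrain, , drop = FALSE], yt, mseed, cw)
        sc <- ln$predict(fitted, x[-itrain, , drop = FALSE])
        ev <- tss(sc, y[-itrain])
        imp <- permutation_importance(ln, fitted, x[itrain, , drop = FALSE],
                                      n_perm)
        models[[counter]] <- list(learner = ln$id, set = s, run = r,
                                  model = fitted, predict = ln$predict,
                                  tss = ev$tss, threshold = ev$threshold,
                                  importance = imp)
      }
    }
  }
  models <- models[!vapply(models, is.null, logical(1))]
  structure(list(models = models, variables = variables, member = member,
                 scenario = scenario, split = split, seed = seed),
            class = "fitted_ensemble")
}

model_frame <- function(world, records, variables, member, label) {
  env <- extract_env_records(world, records, variables, member)
  env <- as.data.frame(env)
  env$.label <- label
  # missing-data policy: records whose environment is incomplete are dropped
  env[stats::complete.cases(env), , drop = FALSE]
}

permutation_importance <- function(learner, fitted, x, n_perm) {
  base <- learner$predict(fitted, x)
  vapply(names(x), function(v) {
    drop <- vapply(seq_len(n_perm), function(p) {
      xp <- x
      xp[[v]] <- sample(xp[[v]])
      pred <- learner$predict(fitted, xp)
      if (stats::sd(pred) == 0 || stats::sd(base) == 0) return(1)
      1 - stats::cor(base, pred)
    }, numeric(1))
    mean(drop)
  }, numeric(1))
}

#' @export
print.fitted_ensemble <- function(x, ...) {
  w <- vapply(x$models, `[[`, numeric(1), "tss")
  cat(sprintf("<fitted_ensemble> %d member models (%s), TSS %.2f-%.2f\n",
              length(x$models),
              paste(unique(vapply(x$models, `[[`, character(1), "learner")),
                    collapse = "/"),
              min(w), max(w)))
  invisible(x)
}

#' Mean variable importance of an ensemble
#'
#' @param ensemble a [fit_ensemble()] result.
#' @return named numeric, mean permutation importance per predictor.
#' @export
ensemble_importance <- function(ensemble) {
  imps <- do.call(rbind, lapply(ensemble$models, `[[`, "importance"))
  colMeans(imps)
}

#' TSS-weighted ensemble prediction on a feature table
#'
#' `suitability = sum(w_i * p_i) / sum(w_i)` with `w_i = max(TSS_i, 0)`;
#' member models with non-positive TSS carry zero weight.
#'
#' @param ensemble a [fit_ensemble()] result.
#' @param x feature data frame (columns = ensemble variables).
#' @return numeric suitability in `[0, 1]`.
#' @export
predict_ensemble <- function(ensemble, x) {
  w <- pmax(vapply(ensemble$models, `[[`, numeric(1), "tss"), 0)
  if (all(w <= 0)) stop("all ensemble weights are <= 0")
  num <- rep(0, nrow(x)); den <- 0
  for (k in seq_along(ensemble$models)) {
    if (w[k] <= 0) next
    m <- ensemble$models[[k]]
    num <- num + w[k] * m$predict(m$model, x)
    den <- den + w[k]
  }
  num / den
}

#' Project an ensemble onto the world grid
#'
#' Predicts suitability per cell and month, then averages over the months of
#' the period. Cells with incomplete environments are `NA`.
#'
#' @param ensemble a [fit_ensemble()] result.
#' @param world a [make_synthetic_world()] result.
#' @param months months of the projection period.
#' @param member,scenario fields to project with.
#' @return an object of class `suitability_map` (values in `[0, 1]`).
#' @export
ensemble_predict <- function(ensemble, world, months,
                             member = world$members[1],
                             scenario = "baseline") {
  nlat <- length(world$lat); nlon <- length(world$lon)
  acc <- matrix(0, nlat, nlon); cnt <- matrix(0L, nlat, nlon)
  for (m in months) {
    x <- month_features(world, ensemble$variables, m, member, scenario)
    ok <- stats::complete.cases(x)
    if (!any(ok)) next
    p <- rep(NA_real_, nrow(x))
    p[ok] <- predict_ensemble(ensemble, x[ok, , drop = FALSE])
    pm <- matrix(p, nlat, nlon)
    hit <- !is.na(pm)
    acc[hit] <- acc[hit] + pm[hit]
    cnt[hit] <- cnt[hit] + 1L
  }
  vals <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  structure(list(lat = world$lat, lon = world$lon, values = vals,
                 member = member, scenario = scenario, months = months),
            class = "suitability_map")
}

month_features <- function(world, variables, month, member, scenario) {
  nlat <- length(world$lat); nlon <- length(world$lon)
  out <- data.frame(row.names = seq_len(nlat * nlon))
  for (v in variables) {
    vals <- switch(v,
      slope = world$slope,
      coast_class = world$coast_class + 0,
      land = world$land + 0,
      matrix(world$fields[[member]][[scenario]][[v]]$values[month, , ],
             nlat, nlon))
    out[[v]] <- as.vector(vals)
  }
  out
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> member=%s scenario=%s months=%s\n",
              x$member, x$scenario, paste(x$months, collapse = ",")))
  cat(sprintf("  mean %.3f over %d defined cells\n",
              mean(x$values, na.rm = TRUE), sum(!is.na(x$values))))
  invisible(x)
}

#' Continuous Boyce index
#'
#' Splits the suitability axis into `n_windows` overlapping windows of the
#' given width, computes the predicted-to-expected ratio
#' `P/E = (share of presence suitabilities in window) / (share of background
#' suitabilities in window)` and returns the Spearman rank correlation
#' between window midpoints and `P/E` over windows with `E > 0`.
#'
#' @param pres_suit suitability values at presences (>= 10 values).
#' @param bg_suit suitability values over the background.
#' @param n_windows number of window midpoints spanning `[0, 1]`.
#' @param width window width.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(pres_suit, bg_suit, n_windows = 101L, width = 0.1) {
  pres_suit <- pres_suit[!is.na(pres_suit)]
  bg_suit <- bg_suit[!is.na(bg_suit)]
  if (length(pres_suit) < 10L) stop("need >= 10 presence suitabilities")
  if (stats::sd(pres_suit) == 0) stop("all presence suitabilities identical")
  mids <- seq(0, 1, length.out = n_windows)
  pe <- vapply(mids, function(m) {
    lo <- m - width / 2; hi <- m + width / 2
    p <- mean(pres_suit >= lo & pres_suit <= hi)
    e <- mean(bg_suit >= lo & bg_suit <= hi)
    if (e == 0) NA_real_ else p / e
  }, numeric(1))
  ok <- !is.na(pe)
  stats::cor(mids[ok], pe[ok], method = "spearman")
}

#' Cross-member coefficient-of-variation map
#'
#' Per-cell population standard deviation divided by the mean of suitability
#' across climate members; undefined (`NA`) where the mean is zero.
#'
#' @param maps list of [ensemble_predict()] results on a shared grid.
#' @return a `suitability_map`-like object whose values are CVs.
#' @export
cv_map <- function(maps) {
  if (length(maps) < 2L) stop("need >= 2 maps")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(ref$lat, m$lat)) ||
        !isTRUE(all.equal(ref$lon, m$lon))) stop("grid mismatch")
  }
  arr <- simplify2array(lapply(maps, `[[`, "values"))
  mu <- apply(arr, c(1, 2), mean)
  sdp <- sqrt(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)))
  cv <- ifelse(!is.na(mu) & mu > 0, sdp / mu, NA_real_)
  structure(list(lat = ref$lat, lon = ref$lon, values = cv,
                 member = "ensemble", scenario = ref$scenario,
                 months = ref$months),
            class = "suitability_map")
}
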