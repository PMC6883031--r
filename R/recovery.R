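#' Parameter-recovery experiment for the distribution-model ensemble
#'
#' Samples presences from a known logistic suitability over two predictors,
#' fits the pseudo-absence ensemble, and measures (i) the True Skill
#' Statistic of the TSS-weighted ensemble on an independently drawn
#' validation presence/pseudo-absence sample and (ii) the continuous Boyce
#' index of the projected suitability map against the training presences.
#' Optionally evaluates the Boyce index under the uniform-sampling null
#' (presences drawn ignoring suitability), which should score near zero.
#'
#' @param world a [make_synthetic_world()] result.
#' @param seed RNG seed for the whole experiment.
#' @param coefs generating suitability coefficients (two predictors by
#'   default).
#' @param n_presence training presences (default 300).
#' @param pa_sets,pa_n,runs ensemble size knobs.
#' @param months season months.
#' @param member,scenario fields used.
#' @param null_mode `"none"`, `"uniform"` or `"inverted"` presence sampling
#'   for the Boyce evaluation.
#' @return list with `tss_holdout`, `boyce`, `n_models`, `importance`.
#' @export
recovery_experiment <- function(world, seed,
                                coefs = c(intercept = 0.5, airtemp = 0.25,
                                          slope = -1.2),
                                n_presence = 300L, pa_sets = 3L, pa_n = 300L,
                                runs = 2L, months = c(10:12, 1:2),
                                member = world$members[1],
                                scenario = "baseline",
                                null_mode = c("none", "uniform",
                                              "inverted")) {
  null_mode <- match.arg(null_mode)
  variables <- setdiff(sub("_sq$", "", names(coefs)), "intercept")
  seed <- as.integer(seed)
  pres <- sample_occurrences(world, coefs, n_presence, months = months,
                             member = member, scenario = scenario,
                             seed = seed)
  pa <- sample_pa_buffer(pres, world, variables, n = pa_n, sets = pa_sets,
                         seed = seed + 1L, member = member,
                         scenario = scenario)
  pa <- timestamp_pa(pa, pres, seed = seed + 2L)
  ens <- fit_ensemble(pres, pa, world, variables, runs = runs,
                      seed = seed + 3L, member = member, scenario = scenario)

  # independent validation draw: fresh presences vs a fresh buffer sample
  vpres <- sample_occurrences(world, coefs, 150L, months = months,
                              member = member, scenario = scenario,
                              seed = seed + 4L)
  vpa <- sample_pa_buffer(pres, world, variables, n = 150L, sets = 1L,
                          seed = seed + 5L, member = member,
                          scenario = scenario)
  vpa <- timestamp_pa(vpa, pres, seed = seed + 6L)[[1]]
  vx <- rbind(model_frame(world, vpres, variables, member, 1L),
              model_frame(world, vpa, variables, member, 0L))
  scores <- predict_ensemble(ens, vx[variables])
  tss_holdout <- tss(scores, vx$.label)$tss

  map <- ensemble_predict(ens, world, months, member, scenario)
  eval_pres <- switch(null_mode,
    none = pres,
    uniform = sample_occurrences(world, coefs, n_presence, months = months,
                                 member = member, scenario = scenario,
                                 seed = seed + 7L, uniform = TRUE),
    inverted = sample_occurrences(world, coefs, n_presence, months = months,
                                  member = member, scenario = scenario,
                                  seed = seed + 7L, invert = TRUE))
  ps <- vapply(seq_len(nrow(eval_pres)), function(k) {
    map$values[nearest_index(world$lat, eval_pres$lat[k]),
               nearest_index(world$lon, eval_pres$lon[k])]
  }, numeric(1))
  bg <- map$values[!is.na(map$values)]
  list(tss_holdout = tss_holdout,
       boyce = boyce_index(ps, bg),
       n_models = length(ens$models),
       importance = ensemble_importance(ens))
}
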