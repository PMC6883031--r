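#' Default pipeline configuration
#'
#' Parameters of the end-to-end demonstration run: a circumpolar band grid
#' with two continents and an open Arctic basin, two climate members under a
#' strong-warming future, a winter-warm Pacific sector (the inter-basin
#' asymmetry the strategy comparison hinges on), the published decision
#' thresholds (5% range overlap, suitability 0.9, 200 km foraging radius,
#' 250 km residency radius, 100 km consecutive-land limit, 13 m/s flight
#' speed, one-month migration) and desk-scale ensemble sizes.
#'
#' @param seed integer seed driving every random stage.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    grid = list(lat = c(40, 90), lon = c(-180, 180), spacing = c(2.5, 9)),
    members = c("m1", "m2"),
    warming = c(m1 = 3, m2 = 4),
    winter_warm_sector = list(
      # warm midlatitude North Pacific: the inter-basin winter asymmetry
      list(lon = c(120, 180), lat = c(40, 65), months = c(11:12, 1:3),
           delta = 10),
      # warm-inflow tongue reaching the colony sector (Barents-like)
      list(lon = c(10, 100), lat = c(60, 90), months = c(9:12, 1:3),
           delta = 8)),
    colony = c(lon = 55, lat = 77),
    atlantic_sector = list(lon = c(-60, 10), lat = c(40, 70)),
    pacific_sector = list(lon = c(120, 180), lat = c(40, 65)),
    species = list(min_overlap = 5),
    sdm = list(
      variables = c("airtemp", "ice", "slope"),
      true_coefs = c(intercept = 2.1, airtemp = -0.2, airtemp_sq = -0.02),
      n_presence = 150L, months = c(10:12, 1:2),
      pa_n = 300L, pa_sets = 2L, runs = 2L),
    habitat = list(theta = 0.9, breeding_radius = 200, residency_radius = 250),
    flyway = list(land_limit = 100, speed_ms = 13, duration_days = 30,
                  ice_threshold = 0.5, beta = 10),
    energetics = list(bird = bird_spec(), wind = 6, cloud = 0.6,
                      rest_budget = c(on_water = 0.9, rest_air = 0.1)),
    stages = c(world = TRUE, species = TRUE, sdm = TRUE, habitats = TRUE,
               routes = TRUE, energetics = TRUE, compare = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the corresponding [default_config()]
#' entries (one level deep).
#'
#' @param path YAML file.
#' @param seed fallback seed.
#' @return configuration list.
#' @export
read_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(if (!is.null(user$seed)) user$seed else seed)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

pipe_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  pipe_log(quiet, name, "done in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the full analysis pipeline
#'
#' Executes synthetic world generation, species screening, predictor
#' screening and distribution-model fitting, habitat derivation, route
#' construction and the per-strategy energy budgets, then compares the
#' migratory strategies. Artifacts (JSON reports, NetCDF maps, GeoJSON
#' routes, CSV tables) and a manifest with parameters, seeds and per-file
#' checksums are written under `outdir`.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run"),
                         quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  on <- function(s) isTRUE(config$stages[[s]])
  skipped <- character()

  if (on("world")) {
    res$world <- run_stage("synth-world", quiet, make_synthetic_world(
      grid = config$grid, members = config$members, warming = config$warming,
      seed = config$seed, winter_warm_sector = config$winter_warm_sector))
  } else skipped <- c(skipped, "world")

  if (on("species")) {
    res$screening <- run_stage("screen-species", quiet, {
      tb <- synthetic_species_table()
      sc <- screen_species(tb, config$species$min_overlap)
      write_screen_report(sc, file.path(outdir, "species_screen.json"))
      sc
    })
  } else skipped <- c(skipped, "species")

  if (on("sdm") && !is.null(res$world)) {
    res$sdm <- run_stage("fit-sdm", quiet,
                         pipeline_sdm(res$world, config, outdir))
  } else skipped <- c(skipped, "sdm")

  if (on("habitats") && !is.null(res$sdm)) {
    res$habitats <- run_stage("derive-habitats", quiet,
                              pipeline_habitats(res$world, res$sdm, config,
                                                outdir))
  } else skipped <- c(skipped, "habitats")

  if (on("routes") && !is.null(res$habitats)) {
    res$routes <- run_stage("build-routes", quiet,
                            pipeline_routes(res$world, res$habitats, config,
                                            outdir))
  } else skipped <- c(skipped, "routes")

  if (on("energetics") && !is.null(res$routes)) {
    res$budgets <- run_stage("energetics", quiet,
                             pipeline_energetics(res$world, res$habitats,
                                                 res$routes, config, outdir))
  } else skipped <- c(skipped, "energetics")

  if (on("compare") && !is.null(res$budgets)) {
    res$comparison <- run_stage("compare", quiet, {
      cmp <- compare_strategies(res$budgets)
      write_comparison(cmp, outdir)
      cmp
    })
  } else skipped <- c(skipped, "compare")

  res$skipped <- skipped
  res$manifest <- write_manifest(config, outdir, skipped)
  invisible(res)
}

pipeline_sdm <- function(world, config, outdir) {
  sc <- config$sdm
  # predictor screening on the candidate-cell design matrix
  cand <- candidate_cells(world, c("airtemp", "sst", "ice", "slope"),
                          world$members[1], "baseline")
  screen <- screen_predictors(cand[c("airtemp", "sst", "ice", "slope")])
  variables <- intersect(sc$variables, screen$kept)
  if (length(variables) < 2L) variables <- sc$variables
  presences <- sample_occurrences(world, sc$true_coefs, sc$n_presence,
                                  months = sc$months, seed = config$seed)
  pa <- sample_pa_envelope(presences, world, variables, n = sc$pa_n,
                           sets = sc$pa_sets, seed = config$seed + 1L)
  pa <- timestamp_pa(pa, presences, seed = config$seed + 2L)
  ens <- fit_ensemble(presences, pa, world, variables, runs = sc$runs,
                      seed = config$seed + 3L)
  base_map <- ensemble_predict(ens, world, sc$months, world$members[1],
                               "baseline")
  pres_suit <- vapply(seq_len(nrow(presences)), function(k) {
    base_map$values[nearest_index(world$lat, presences$lat[k]),
                    nearest_index(world$lon, presences$lon[k])]
  }, numeric(1))
  boyce <- boyce_index(pres_suit,
                       base_map$values[!is.na(base_map$values)])
  maps <- lapply(stats::setNames(world$members, world$members), function(m) {
    ensemble_predict(ens, world, sc$months, m, "future")
  })
  cvm <- if (length(maps) >= 2L) cv_map(maps) else NULL
  meta <- list(variables = variables,
               screened_out = screen$report$column,
               n_models = length(ens$models),
               tss = vapply(ens$models, `[[`, numeric(1), "tss"),
               importance = as.list(ensemble_importance(ens)),
               boyce_baseline = boyce)
  jsonlite::write_json(meta, file.path(outdir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  save_map_nc(base_map, world, file.path(outdir, "suitability_baseline.nc"))
  list(ensemble = ens, variables = variables, presences = presences,
       baseline_map = base_map, future_maps = maps, cv = cvm, boyce = boyce,
       screen = screen)
}

save_map_nc <- function(map, world, path) {
  vals <- array(map$values, dim = c(1, length(map$lat), length(map$lon)))
  gf <- grid_field("suitability", "index", map$lat, map$lon,
                   data.frame(year = world$years[[map$scenario]],
                              month = map$months[1]),
                   vals, member = map$member, scenario = map$scenario)
  write_grid_nc(list(suitability = gf), path,
                byte_layers = list(land = world$land))
}

pipeline_habitats <- function(world, sdm, config, outdir) {
  theta <- config$habitat$theta
  colony <- config$colony
  # the colony is a known breeding site; a one-cell breeding mask anchors
  # the residency rule
  bmask <- matrix(FALSE, length(world$lat), length(world$lon))
  bmask[nearest_index(world$lat, colony[["lat"]]),
        nearest_index(world$lon, colony[["lon"]])] <- TRUE
  breeding <- habitat_mask(world$lat, world$lon, bmask, "breeding_area")
  wintering <- lapply(sdm$future_maps, threshold_suitable, theta = theta)
  residency <- lapply(wintering, function(w) {
    residency_area(breeding, w, config$habitat$residency_radius)
  })
  for (m in names(wintering)) {
    write_mask_geojson(wintering[[m]],
                       file.path(outdir, sprintf("wintering_%s.geojson", m)))
  }
  list(breeding = breeding, wintering = wintering, residency = residency)
}

# cells suitable for every climate member, or for at least one member where
# the member maps have no overlap at all
consensus_cells <- function(maps, theta) {
  arr <- simplify2array(lapply(maps, `[[`, "values"))
  all_ok <- apply(arr, c(1, 2), function(v) all(!is.na(v) & v > theta))
  any_ok <- apply(arr, c(1, 2), function(v) any(!is.na(v) & v > theta))
  list(all = all_ok, any = any_ok)
}

pipeline_routes <- function(world, habitats, config, outdir) {
  colony <- c(config$colony[["lon"]], config$colony[["lat"]])
  maps <- lapply(names(habitats$wintering), function(m) {
    structure(list(lat = world$lat, lon = world$lon,
                   values = ifelse(habitats$wintering[[m]]$mask, 1, 0)),
              class = "suitability_map")
  })
  cons <- consensus_cells(maps, 0.5)
  cells_all <- mask_cells(habitat_mask(world$lat, world$lon, cons$all,
                                       "wintering"))
  cells_any <- mask_cells(habitat_mask(world$lat, world$lon, cons$any,
                                       "wintering"))
  if (nrow(cells_any) == 0L) stop("no suitable wintering cells for any member")
  insec <- function(cells, sec) {
    cells[cells$lon >= sec$lon[1] & cells$lon <= sec$lon[2] &
            cells$lat >= sec$lat[1] & cells$lat <= sec$lat[2], ]
  }
  sector_cells <- function(sec, what) {
    out <- insec(cells_all, sec)             # prefer cross-member consensus
    if (nrow(out) == 0L) out <- insec(cells_any, sec)
    if (nrow(out) == 0L) {
      stop("no suitable wintering cells in the ", what, " sector")
    }
    out
  }

  atl <- sector_cells(config$atlantic_sector, "Atlantic")
  atl_mask <- matrix(FALSE, length(world$lat), length(world$lon))
  atl_mask[cbind(atl$i, atl$j)] <- TRUE
  current_dest <- wintering_centroid(
    habitat_mask(world$lat, world$lon, atl_mask, "wintering"),
    land = world$land)

  pac <- sector_cells(config$pacific_sector, "Pacific")
  d <- gc_distance(colony[1], colony[2], pac$lon, pac$lat)
  trans_dest <- c(lon = pac$lon[which.min(d)], lat = pac$lat[which.min(d)])

  fl <- config$flyway
  routes <- list()
  for (m in world$members) {
    routes[[m]] <- list(
      current_out = direct_route(colony, current_dest, world, 9, m, "future",
                                 fl$land_limit),
      trans_out = direct_route(colony, trans_dest, world, 9, m, "future",
                               fl$land_limit),
      trans_return_direct = direct_route(trans_dest, colony, world, 3, m,
                                         "future", fl$land_limit),
      trans_return_peripheral = peripheral_route(
        trans_dest, colony, world, 3, m, "future", fl$land_limit,
        ice_threshold = fl$ice_threshold, beta = fl$beta))
  }
  write_route_geojson(routes[[1]]$trans_out,
                      file.path(outdir, "route_transarctic_sept.geojson"))
  write_route_geojson(routes[[1]]$trans_return_peripheral,
                      file.path(outdir, "route_transarctic_march.geojson"))
  list(routes = routes, current_dest = current_dest, trans_dest = trans_dest)
}

pipeline_energetics <- function(world, habitats, routes, config, outdir) {
  colony <- c(config$colony[["lon"]], config$colony[["lat"]])
  en <- config$energetics
  fl <- config$flyway
  strategies <- c("current", "transarctic", "transarctic_peripheral",
                  "residency")
  series <- lapply(stats::setNames(strategies, strategies), function(s) list())
  for (m in world$members) {
    rt <- routes$routes[[m]]
    res_mask <- habitats$residency[[m]]
    res_ok <- any(res_mask$mask)
    res_dest <- if (res_ok) {
      wintering_centroid(res_mask, land = world$land)
    } else colony
    defs <- list(
      current = strategy_scenario("current", colony, routes$current_dest,
                                  rt$current_out),
      transarctic = strategy_scenario("transarctic", colony,
                                      routes$trans_dest, rt$trans_out,
                                      rt$trans_return_direct),
      transarctic_peripheral = strategy_scenario(
        "transarctic_peripheral", colony, routes$trans_dest, rt$trans_out,
        rt$trans_return_peripheral),
      residency = strategy_scenario("residency", colony, res_dest,
                                    feasible = res_ok))
    for (s in strategies) {
      series[[s]][[m]] <- strategy_month_series(
        defs[[s]], m, world, en$bird, "future",
        rest_budget = en$rest_budget, wind = en$wind, cloud = en$cloud,
        speed_ms = fl$speed_ms, duration_days = fl$duration_days)
    }
  }
  budgets <- list()
  for (s in names(series)) {
    budgets[[s]] <- tryCatch(ensemble_stats(series[[s]]), error = function(e) NULL)
  }
  budgets <- Filter(Negate(is.null), budgets)
  if (length(budgets) == 0L) stop("no strategy feasible for any member")
  tab <- do.call(rbind, lapply(names(budgets), function(s) {
    data.frame(strategy = s, month = budgets[[s]]$months,
               kj_day = budgets[[s]]$kj_day_mean,
               kj_day_sd = budgets[[s]]$kj_day_sd)
  }))
  utils::write.csv(tab, file.path(outdir, "monthly_energy.csv"),
                   row.names = FALSE)
  budgets
}

write_manifest <- function(config, outdir, skipped) {
  files <- list.files(outdir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    package = "polarflyway",
    version = as.character(utils::packageVersion("polarflyway")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[setdiff(names(config), "stages")],
    skipped_stages = if (length(skipped)) skipped else character(),
    checksums = as.list(stats::setNames(unname(sums), files)))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest
}
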