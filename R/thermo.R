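#' Bird morphology and physiology specification
#'
#' Parameters of the steady-state heat-balance model. The body is a
#' horizontal cylinder of core diameter `core_d` and length `len` wrapped in
#' a plumage shell of thickness `plumage_depth` and effective conductivity
#' `k_plumage`. Defaults are synthetic placeholders sized for a small
#' (~160 g) diving seabird and are meant to be overridden per species.
#'
#' @param mass_kg body mass (kg).
#' @param core_d core cylinder diameter (m).
#' @param len cylinder length (m).
#' @param plumage_depth plumage shell thickness (m).
#' @param k_plumage effective plumage conductivity (W m-1 K-1).
#' @param t_core core temperature (degC).
#' @param emissivity longwave surface emissivity (0-1).
#' @param absorptivity shortwave absorptivity (0-1).
#' @param basal_w basal metabolic floor (W).
#' @param flight_w total metabolic power in flight (W).
#' @param immersion ventral fraction of the surface immersed when on water.
#' @param e_resp respiratory evaporative share of metabolic production.
#' @param rad_frac radiating fraction of the outer area (view-factor
#'   allowance).
#' @return an object of class `bird_spec`.
#' @export
bird_spec <- function(mass_kg = 0.16, core_d = 0.055, len = 0.18,
                      plumage_depth = 0.012, k_plumage = 0.045,
                      t_core = 40, emissivity = 0.95, absorptivity = 0.85,
                      basal_w = 1.8, flight_w = 11, immersion = 0.55,
                      e_resp = 0.05, rad_frac = 0.8) {
  spec <- list(mass_kg = mass_kg, core_d = core_d, len = len,
               plumage_depth = plumage_depth, k_plumage = k_plumage,
               t_core = t_core, emissivity = emissivity,
               absorptivity = absorptivity, basal_w = basal_w,
               flight_w = flight_w, immersion = immersion, e_resp = e_resp,
               rad_frac = rad_frac)
  if (!all(vapply(spec, is.numeric, logical(1)))) {
    stop("all bird_spec fields must be numeric")
  }
  stopifnot(mass_kg > 0, core_d > 0, len > 0, plumage_depth > 0,
            k_plumage > 0, basal_w > 0, flight_w > 0,
            immersion >= 0, immersion <= 1, e_resp >= 0, e_resp < 1,
            emissivity >= 0, emissivity <= 1, rad_frac > 0, rad_frac <= 1)
  structure(spec, class = "bird_spec")
}

#' Microclimate at the animal
#'
#' @param airtemp air temperature (degC).
#' @param watertemp water temperature (degC, floored at -1.8).
#' @param wind wind speed (m/s).
#' @param cloud cloud fraction (0-1).
#' @param shortwave incident shortwave flux (W m-2; 0 in polar night).
#' @param current water current speed past the body (m/s).
#' @return an object of class `microclimate`, including the derived
#'   effective sky temperature.
#' @export
microclimate <- function(airtemp, watertemp = max(airtemp, -1.8), wind = 5,
                         cloud = 0.5, shortwave = 0, current = 0.3) {
  stopifnot(wind >= 0, cloud >= 0, cloud <= 1, shortwave >= 0)
  watertemp <- max(watertemp, -1.8)
  structure(list(airtemp = airtemp, watertemp = watertemp, wind = wind,
                 cloud = cloud, shortwave = shortwave, current = current,
                 skytemp = sky_temperature(airtemp, cloud)),
            class = "microclimate")
}

#' Effective sky temperature
#'
#' Clear-sky radiative temperature is taken 20 K below air temperature and
#' overcast sky equals air temperature, blended linearly in cloud fraction.
#'
#' @param airtemp air temperature (degC).
#' @param cloud cloud fraction (0-1).
#' @return sky temperature (degC).
#' @export
sky_temperature <- function(airtemp, cloud) {
  stopifnot(cloud >= 0, cloud <= 1)
  airtemp - 20 * (1 - cloud)
}

# fluid thermophysical properties at film temperature (degC):
# linear fits adequate over the polar range (-40..30 degC)
fluid_props <- function(fluid, temp) {
  if (fluid == "air") {
    list(k = 0.0243 + 7.2e-5 * temp,          # W m-1 K-1
         nu = 1.33e-5 + 9.0e-8 * temp,        # m2 s-1
         pr = 0.71)
  } else {
    t <- max(temp, -1.8)
    list(k = 0.563 + 1.8e-3 * t,
         nu = pmax(1.79e-6 - 0.04e-6 * t, 0.8e-6),
         pr = pmax(13.4 - 0.32 * t, 6))
  }
}

# Hilpert cylinder-in-crossflow constants by Reynolds regime
HILPERT <- data.frame(re_lo = c(0.4, 4, 40, 4000, 40000),
                      re_hi = c(4, 40, 4000, 40000, 400000),
                      c = c(0.989, 0.911, 0.683, 0.193, 0.027),
                      n = c(0.330, 0.385, 0.466, 0.618, 0.805))

#' Forced-convection coefficient for a cylinder in crossflow
#'
#' Hilpert correlation `Nu = C Re^n Pr^(1/3)` with piecewise constants,
#' evaluated with fluid properties at the film temperature. In air a
#' free-convection floor `h_min` applies (calm-air limit). Reynolds numbers
#' outside the tabulated range fall back to the nearest regime with a
#' warning.
#'
#' @param diameter outer diameter (m).
#' @param speed fluid speed (m/s).
#' @param fluid `"air"` or `"water"`.
#' @param temp fluid (film) temperature (degC).
#' @param h_min free-convection floor in air (W m-2 K-1).
#' @return convective coefficient (W m-2 K-1).
#' @export
convective_coefficient <- function(diameter, speed, fluid = "air", temp = 0,
                                   h_min = 3) {
  stopifnot(diameter > 0, speed >= 0)
  p <- fluid_props(fluid, temp)
  if (speed <= 0) {
    return(if (fluid == "air") h_min else 0.5 * p$k / diameter * 10)
  }
  re <- speed * diameter / p$nu
  row <- which(re >= HILPERT$re_lo & re < HILPERT$re_hi)
  if (length(row) == 0L) {
    row <- if (re < HILPERT$re_lo[1]) 1L else nrow(HILPERT)
    warning(sprintf("Re = %.3g outside tabulated range; using nearest regime",
                    re))
  }
  nu <- HILPERT$c[row] * re^HILPERT$n[row] * p$pr^(1 / 3)
  h <- nu * p$k / diameter
  if (fluid == "air") max(h, h_min) else h
}

SIGMA <- 5.670374419e-8

#' Steady-state metabolic rate in a microclimate
#'
#' Solves the heat balance of a plumage-wrapped cylinder: metabolic heat
#' conducted through the plumage shell,
#' `2 pi k L (Tb - Ts) / ln(r_out / r_in)`, must equal the external loss at
#' the plumage surface. At rest in air the loss is convection to air plus
#' longwave exchange with the sky minus absorbed shortwave; on water the
#' surface is split by the immersion fraction, the immersed part exchanging
#' with water by convection only and the emergent part with air and sky.
#' The surface temperature is found by bisection; the required metabolic
#' rate is the net production inflated by the respiratory evaporative share,
#' floored at the basal rate (the thermoneutral case).
#'
#' @param bird a [bird_spec()].
#' @param micro a [microclimate()].
#' @param activity `"rest-air"` or `"on-water"`.
#' @param tol relative bisection tolerance on surface temperature.
#' @param maxit maximum bisection iterations.
#' @return list with `metabolic_w`, `surface_temp`, `net_w`, and flags
#'   `thermoneutral` and `heat_stress`.
#' @export
solve_steady_state <- function(bird, micro, activity = c("rest-air",
                                                         "on-water"),
                               tol = 1e-6, maxit = 200L) {
  activity <- match.arg(activity)
  r_in <- bird$core_d / 2
  r_out <- r_in + bird$plumage_depth
  a_out <- 2 * pi * r_out * bird$len
  k_cond <- 2 * pi * bird$k_plumage * bird$len / log(r_out / r_in)
  conduction <- function(ts) k_cond * (bird$t_core - ts)

  if (activity == "rest-air") {
    h_a <- convective_coefficient(2 * r_out, micro$wind, "air",
                                  (micro$airtemp + bird$t_core) / 2)
    loss <- function(ts) {
      h_a * a_out * (ts - micro$airtemp) +
        bird$emissivity * SIGMA * bird$rad_frac * a_out *
          ((ts + 273.15)^4 - (micro$skytemp + 273.15)^4) -
        bird$absorptivity * micro$shortwave * 2 * r_out * bird$len
    }
    t_env_min <- min(micro$airtemp, micro$skytemp)
  } else {
    h_a <- convective_coefficient(2 * r_out, micro$wind, "air",
                                  (micro$airtemp + bird$t_core) / 2)
    h_w <- convective_coefficient(2 * r_out, micro$current, "water",
                                  micro$watertemp)
    f <- bird$immersion
    loss <- function(ts) {
      f * h_w * a_out * (ts - micro$watertemp) +
        (1 - f) * (h_a * a_out * (ts - micro$airtemp) +
                     bird$emissivity * SIGMA * bird$rad_frac * a_out *
                       ((ts + 273.15)^4 - (micro$skytemp + 273.15)^4)) -
        (1 - f) * bird$absorptivity * micro$shortwave * 2 * r_out * bird$len
    }
    t_env_min <- min(micro$airtemp, micro$watertemp, micro$skytemp)
  }

  g <- function(ts) conduction(ts) - loss(ts)
  lo <- t_env_min - 5; hi <- bird$t_core
  glo <- g(lo); ghi <- g(hi)
  if (ghi > 0) {
    # environment hotter than the core: no positive-gradient solution
    return(list(metabolic_w = bird$basal_w, surface_temp = bird$t_core,
                net_w = 0, closure = 0, thermoneutral = TRUE,
                heat_stress = TRUE))
  }
  it <- 0L
  while (it < maxit) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm > 0) lo <- mid else hi <- mid
    it <- it + 1L
    if ((hi - lo) < tol * max(1, abs(hi))) {
      if (abs(gm) < 1e-8 * max(abs(loss(mid)), 1e-6)) break
    }
  }
  if (it >= maxit && (hi - lo) > 1e-3) {
    stop("steady-state solver failed to converge")
  }
  ts <- (lo + hi) / 2
  net <- conduction(ts)
  closure <- abs(net - loss(ts)) / max(abs(loss(ts)), 1e-9)
  heat_stress <- net < 0
  m <- net / (1 - bird$e_resp)
  thermoneutral <- m <= bird$basal_w
  list(metabolic_w = max(m, bird$basal_w), surface_temp = ts, net_w = net,
       closure = closure, thermoneutral = thermoneutral,
       heat_stress = heat_stress)
}

#' Daily energy expenditure from an activity budget
#'
#' `E = 86.4 (f_fly P_fly + f_water M_water + f_rest M_rest)` in kJ/day,
#' with steady-state metabolic rates computed for the on-water and
#' resting-in-air states; flight thermoregulation is assumed covered by the
#' flight power.
#'
#' @param bird a [bird_spec()].
#' @param micro a [microclimate()].
#' @param budget named fractions `c(flying, on_water, rest_air)` summing
#'   to 1.
#' @return list with `kj_day` and the component metabolic rates (W).
#' @export
daily_energy <- function(bird, micro, budget = c(flying = 0, on_water = 0.9,
                                                 rest_air = 0.1)) {
  if (abs(sum(budget) - 1) > 1e-8) stop("activity budget must sum to 1")
  if (any(budget < 0 | budget > 1)) stop("budget fractions must be in [0,1]")
  m_water <- if (budget[["on_water"]] > 0) {
    solve_steady_state(bird, micro, "on-water")$metabolic_w
  } else 0
  m_rest <- if (budget[["rest_air"]] > 0) {
    solve_steady_state(bird, micro, "rest-air")$metabolic_w
  } else 0
  kj <- 86.4 * (budget[["flying"]] * bird$flight_w +
                  budget[["on_water"]] * m_water +
                  budget[["rest_air"]] * m_rest)
  list(kj_day = kj, m_water = m_water, m_rest = m_rest,
       m_flight = bird$flight_w)
}
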