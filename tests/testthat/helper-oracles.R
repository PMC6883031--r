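# 5x5 world (2 deg cells) with a two-cell-thick land wall pierced by a
# mid-latitude strait; at these latitudes one wall-interior leg is ~128 km,
# beyond the 100 km consecutive-land limit
strait_world <- function() {
  patterned_world(function(lon, lat) lon > 58 & lon < 62 & abs(lat - 59) > 0.9,
                  spacing = 2, lat = c(54, 64), lon = c(54, 64), seed = 2)
}

# linearized resistance-network oracle: series plumage + film resistance,
# with the radiative coefficient linearized around the mean temperature and
# scaled by the radiating-area fraction
resistance_network_m <- function(bird, micro) {
  r_in <- bird$core_d / 2
  r_out <- r_in + bird$plumage_depth
  a_out <- 2 * pi * r_out * bird$len
  r_pl <- log(r_out / r_in) / (2 * pi * bird$k_plumage * bird$len)
  h <- convective_coefficient(2 * r_out, micro$wind, "air",
                              (micro$airtemp + bird$t_core) / 2)
  tbar <- (bird$t_core + micro$airtemp) / 2 + 273.15
  h_r <- bird$rad_frac * 4 * bird$emissivity * 5.670374419e-8 * tbar^3
  r_film <- 1 / ((h + h_r) * a_out)
  (bird$t_core - micro$airtemp) / (r_pl + r_film) / (1 - bird$e_resp)
}

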