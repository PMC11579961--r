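# Independent oracles used across the suite.

# Daily-mean TOA irradiance by brute-force numerical integration of the
# instantaneous irradiance at 1-minute resolution. Shares only the solar
# declination and distance factor with the closed-form daily mean.
minute_mean_insolation <- function(latitude, day, orbit) {
  dec <- solar_declination(day, orbit)
  rho <- coralight:::distance_factor(day, orbit)
  phi <- latitude * pi / 180
  h <- 2 * pi * (seq_len(1440) - 0.5) / 1440 - pi  # hour angle at minute centres
  inst <- orbit$solar_constant * rho *
    pmax(0, sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(h))
  mean(inst)
}

# Straight-loop, scalar re-implementation of the yearly calcification sum at
# one latitude: every day handled individually, gates via if-statements.
loop_yearly_G <- function(latitude, config, scenario) {
  orbit <- config$orbit
  lp <- config$light
  ndays <- orbit$days_per_year
  es <- numeric(ndays)
  for (d in seq_len(ndays))
    es[d] <- daily_insolation(latitude, d, orbit)$surface_par
  n_dark <- 0L
  for (d in seq_len(ndays)) if (es[d] < lp$E_lim) n_dark <- n_dark + 1L
  fd <- if (is.null(lp$tolerance_days)) 1
        else if (n_dark > lp$tolerance_days) 0 else 1
  cold <- stats::approx(scenario$latitude, scenario$coldest_month_sst,
                        xout = latitude)$y
  warm <- stats::approx(scenario$latitude, scenario$warmest_month_sst,
                        xout = latitude)$y
  ft <- if (cold >= config$envelope$T_min && warm <= config$envelope$T_max) 1
        else 0
  g <- 0
  for (d in seq_len(ndays)) {
    ez <- es[d] * exp(-lp$k_par * lp$z)
    g <- g + config$G_max * tanh(ez / lp$E_k) * fd * ft
  }
  g
}

# Analytic inversion of the cos^p gradient: the lowest multiple of grid_step
# at which T(phi) drops strictly below the threshold.
analytic_crossing <- function(spec, threshold, grid_step = 1) {
  Te <- spec$T_eq_cold; Tp <- spec$T_pole_cold; p <- spec$shape_exponent
  if (threshold <= Tp) return(NA_real_)
  if (threshold > Te) return(0)
  phi_star <- acos(((threshold - Tp) / (Te - Tp))^(1 / p)) * 180 / pi
  lat <- seq(0, 90, by = grid_step)
  cand <- lat[lat > phi_star]
  if (!length(cand)) return(NA_real_)
  min(cand)
}

# An unlimiting, latitudinally constant 26 degC scenario.
constant_scenario <- function(temp = 26, grid_step = 1) {
  lat <- seq(0, 90, by = grid_step)
  temperature_scenario(lat, rep(temp, length(lat)), rep(temp, length(lat)),
                       name = sprintf("constant-%g", temp))
}
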