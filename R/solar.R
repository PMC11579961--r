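# Daily solar geometry and surface PAR, following the classical daily-mean
# insolation formulation from orbital elements (Berger-type solar geometry).

# True solar longitude (radians from vernal equinox) for a day of year.
# Mean longitude advances uniformly; the equation-of-centre expansion in
# eccentricity (to third order) maps it to the true longitude. The vernal
# equinox is anchored at calendar day 80.
solar_longitude <- function(day, orbit) {
  e <- orbit$eccentricity
  w <- deg2rad(orbit$lon_perihelion)
  beta <- sqrt(1 - e^2)
  # mean longitude at the vernal equinox such that lambda(ve_day) = 0
  lm0 <- -2 * ((e / 2 + e^3 / 8) * (1 + beta) * sin(-w) -
                 (e^2 / 4) * (1 / 2 + beta) * sin(-2 * w) +
                 (e^3 / 8) * (1 / 3 + beta) * sin(-3 * w))
  lm <- lm0 + 2 * pi * (day - .vernal_equinox_day) / orbit$days_per_year
  lm + (2 * e - e^3 / 4) * sin(lm - w) +
    (5 / 4) * e^2 * sin(2 * (lm - w)) +
    (13 / 12) * e^3 * sin(3 * (lm - w))
}

# Squared ratio of mean to actual Sun-Earth distance, (a/r)^2.
distance_factor <- function(day, orbit) {
  e <- orbit$eccentricity
  w <- deg2rad(orbit$lon_perihelion)
  lam <- solar_longitude(day, orbit)
  ((1 + e * cos(lam - w)) / (1 - e^2))^2
}

#' Solar declination for a day of year
#'
#' Declination of the Sun, \eqn{\delta = \arcsin(\sin\epsilon \sin\lambda)},
#' where \eqn{\epsilon} is the obliquity and \eqn{\lambda} the true solar
#' longitude derived from the orbital elements. Smooth and periodic over the
#' year, bounded by the obliquity.
#'
#' @param day Day of year (vectorized), in `[1, days_per_year]`.
#' @param orbit An [orbit_config()].
#' @return Declination in radians.
#' @examples
#' solar_declination(80)                # ~0 at the vernal equinox
#' max(solar_declination(1:365))        # ~ obliquity in radians
#' @export
solar_declination <- function(day, orbit = orbit_config()) {
  .check_day(day, orbit)
  asin(sin(deg2rad(orbit$obliquity)) * sin(solar_longitude(day, orbit)))
}

#' Sunset hour angle
#'
#' \eqn{\omega_s = \arccos(-\tan\phi \tan\delta)}, clamped to 0 under polar
#' night (\eqn{-\tan\phi\tan\delta \ge 1}) and to \eqn{\pi} under polar day
#' (\eqn{\le -1}).
#'
#' @param latitude Latitude in degrees, `[-90, 90]` (vectorized).
#' @param declination Solar declination in radians.
#' @return Hour angle in radians, in `[0, pi]`.
#' @examples
#' sunset_hour_angle(0, 0.2)                     # pi/2: 12 h at the equator
#' sunset_hour_angle(80, -23 * pi / 180)         # 0: polar night
#' @export
sunset_hour_angle <- function(latitude, declination) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("'latitude' must lie in [-90, 90]", call. = FALSE)
  x <- -tan(deg2rad(latitude)) * tan(declination)
  acos(pmin(1, pmax(-1, x)))
}

#' Day length from the sunset hour angle
#'
#' @param sunset_hour_angle Hour angle in radians, `[0, pi]`.
#' @return Day length in hours, `[0, 24]` (24 * omega_s / pi).
#' @export
day_length <- function(sunset_hour_angle) {
  if (any(!is.finite(sunset_hour_angle)) ||
      any(sunset_hour_angle < 0) || any(sunset_hour_angle > pi))
    stop("'sunset_hour_angle' must lie in [0, pi]", call. = FALSE)
  24 * sunset_hour_angle / pi
}

#' Daily-mean top-of-atmosphere irradiance
#'
#' The 24-hour mean irradiance on a horizontal surface at the top of the
#' atmosphere,
#' \deqn{\bar{W} = \frac{S_0}{\pi}\left(\frac{a}{r}\right)^2
#'   (\omega_s \sin\phi\sin\delta + \cos\phi\cos\delta\sin\omega_s),}
#' including the Sun--Earth distance factor from the orbital position. Zero
#' during polar night.
#'
#' @inheritParams solar_declination
#' @param latitude Latitude in degrees (scalar or same length as `day`).
#' @return Irradiance in W m^-2 averaged over 24 h.
#' @examples
#' daily_mean_insolation(0, 80, orbit_config(eccentricity = 0))  # ~ S0/pi
#' daily_mean_insolation(80, 355)                                # 0 (polar night)
#' @export
daily_mean_insolation <- function(latitude, day, orbit = orbit_config()) {
  .check_day(day, orbit)
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("'latitude' must lie in [-90, 90]", call. = FALSE)
  dec <- solar_declination(day, orbit)
  phi <- deg2rad(latitude)
  ws <- sunset_hour_angle(latitude, dec)
  out <- orbit$solar_constant / pi * distance_factor(day, orbit) *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  pmax(out, 0)
}

#' Surface PAR photon flux from daily-mean irradiance
#'
#' Converts a 24-hour-mean top-of-atmosphere irradiance to the daylight-hours
#' mean surface PAR photon flux:
#' \deqn{E_{surface} = \bar{W} \cdot c_{PAR} \cdot 24 / L}
#' where \eqn{c_{PAR}} is `orbit$par_conversion` (umol photons per Joule of
#' shortwave) and \eqn{L} the day length in hours. The daily photon dose is
#' thus spread over the hours with daylight, matching the convention in which
#' light thresholds (e.g. the dark-day threshold E_lim) are fluxes sustained
#' over the photoperiod. `E_surface` is zero exactly when the day length is
#' zero; conversion is linear in the irradiance.
#'
#' @param toa_mean_irradiance 24-h mean irradiance, W m^-2 (>= 0).
#' @param orbit An [orbit_config()].
#' @param day_length_hours Day length in hours, `[0, 24]`. The default (24)
#'   makes the function a plain linear conversion by `par_conversion`.
#' @return PAR photon flux in umol m^-2 s^-1.
#' @seealso [daily_insolation()] which assembles the full per-day record.
#' @export
surface_par <- function(toa_mean_irradiance, orbit = orbit_config(),
                        day_length_hours = 24) {
  if (any(!is.finite(toa_mean_irradiance)) || any(toa_mean_irradiance < 0))
    stop("'toa_mean_irradiance' must be non-negative", call. = FALSE)
  if (any(day_length_hours < 0) || any(day_length_hours > 24))
    stop("'day_length_hours' must lie in [0, 24]", call. = FALSE)
  ifelse(day_length_hours > 0,
         toa_mean_irradiance * orbit$par_conversion * 24 / day_length_hours,
         0)
}

#' Per-day solar geometry and surface PAR at a latitude
#'
#' Assembles, for one latitude and a set of days, the declination, sunset hour
#' angle, day length, daily-mean top-of-atmosphere irradiance, and daylight-
#' mean surface PAR flux.
#'
#' @param latitude Latitude in degrees.
#' @param day Vector of days of year; defaults to the whole year.
#' @param orbit An [orbit_config()].
#' @return A data frame with columns `latitude`, `day`, `declination` (rad),
#'   `sunset_hour_angle` (rad), `day_length` (h), `toa_mean_irradiance`
#'   (W m^-2) and `surface_par` (umol m^-2 s^-1).
#' @examples
#' ins <- daily_insolation(45)
#' range(ins$day_length)
#' @export
daily_insolation <- function(latitude, day = NULL, orbit = orbit_config()) {
  if (is.null(day)) day <- seq_len(orbit$days_per_year)
  .check_day(day, orbit)
  dec <- solar_declination(day, orbit)
  ws <- sunset_hour_angle(latitude, dec)
  dl <- day_length(ws)
  toa <- daily_mean_insolation(latitude, day, orbit)
  data.frame(latitude = latitude, day = day, declination = dec,
             sunset_hour_angle = ws, day_length = dl,
             toa_mean_irradiance = toa,
             surface_par = surface_par(toa, orbit, dl))
}

#' Year-long surface PAR series for one latitude
#'
#' @inheritParams daily_insolation
#' @return Numeric vector of length `days_per_year`: daylight-mean surface PAR
#'   (umol m^-2 s^-1) for each day.
#' @export
surface_par_series <- function(latitude, orbit = orbit_config()) {
  daily_insolation(latitude, orbit = orbit)$surface_par
}

#' Surface PAR for a latitude grid
#'
#' @param latitudes Vector of latitudes in degrees (default the model grid,
#'   0-90 at 1 degree).
#' @param orbit An [orbit_config()].
#' @return Matrix `length(latitudes) x days_per_year` of daylight-mean surface
#'   PAR (umol m^-2 s^-1); rows named by latitude.
#' @export
surface_par_grid <- function(latitudes = 0:90, orbit = orbit_config()) {
  out <- t(vapply(latitudes, surface_par_series,
                  numeric(orbit$days_per_year), orbit = orbit))
  rownames(out) <- latitudes
  out
}

#' Equinox and solstice days located from the orbital longitude
#'
#' Finds the integer days of year closest to true solar longitudes 0, 90, 180
#' and 270 degrees, i.e. the vernal equinox, June solstice, autumnal equinox
#' and December solstice. Valid for any configured orbit.
#'
#' @param orbit An [orbit_config()].
#' @return Named integer vector with elements `vernal_equinox`,
#'   `june_solstice`, `autumnal_equinox`, `december_solstice`.
#' @export
orbital_event_days <- function(orbit = orbit_config()) {
  days <- seq_len(orbit$days_per_year)
  lam <- solar_longitude(days, orbit) %% (2 * pi)
  pick <- function(target) {
    d <- abs(lam - target)
    days[which.min(pmin(d, 2 * pi - d))]
  }
  c(vernal_equinox = pick(0), june_solstice = pick(pi / 2),
    autumnal_equinox = pick(pi), december_solstice = pick(3 * pi / 2))
}
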