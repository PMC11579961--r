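#' Orbital and solar configuration
#'
#' Bundles the orbital elements and radiation constants that drive the daily
#' insolation engine. Defaults are the modern orbit: eccentricity 0.0167,
#' obliquity 23.44 degrees, longitude of perihelion 282.95 degrees (measured
#' from the vernal equinox), solar constant 1361 W m^-2, and a 365-day year
#' with no leap days. Day-of-year 1 is January 1 and the vernal equinox falls
#' on day 80 (March 21).
#'
#' @param eccentricity Orbital eccentricity, dimensionless, in `[0, 0.1)`.
#' @param obliquity Axial tilt in degrees, in `(0, 90)`.
#' @param lon_perihelion Longitude of perihelion in degrees, measured from the
#'   vernal equinox (geocentric solar longitude at perihelion).
#' @param solar_constant Total solar irradiance at 1 AU, W m^-2.
#' @param days_per_year Integer number of days in the model year.
#' @param par_conversion Effective conversion from top-of-atmosphere shortwave
#'   energy to surface PAR photon flux, in umol photons per Joule. It folds the
#'   PAR fraction of shortwave, the energy-to-photon conversion (about
#'   4.6 umol J^-1 of PAR) and bulk atmospheric/surface losses into a single
#'   constant applied to the daylight-hours mean irradiance; see
#'   [surface_par()]. The default (0.4075 umol J^-1) is calibrated so that the
#'   dark-day threshold fitted against the fossil-record reef cutoff at 50
#'   degrees latitude equals 105 umol m^-2 s^-1 (see the package vignette).
#'
#' @return An object of class `orbit_config` (a named list of the validated
#'   fields).
#' @seealso [daily_insolation()], [solar_declination()]
#' @examples
#' orbit_config()
#' orbit_config(eccentricity = 0)  # circular orbit, exact seasonal symmetry
#' @export
orbit_config <- function(eccentricity = 0.0167,
                         obliquity = 23.44,
                         lon_perihelion = 282.95,
                         solar_constant = 1361,
                         days_per_year = 365L,
                         par_conversion = 0.4075) {
  stopifnot(is.numeric(eccentricity), length(eccentricity) == 1L)
  if (eccentricity < 0 || eccentricity >= 0.1)
    stop("'eccentricity' must lie in [0, 0.1)", call. = FALSE)
  if (!is.numeric(obliquity) || obliquity <= 0 || obliquity >= 90)
    stop("'obliquity' must lie in (0, 90) degrees", call. = FALSE)
  if (!is.numeric(solar_constant) || solar_constant <= 0)
    stop("'solar_constant' must be positive", call. = FALSE)
  days_per_year <- as.integer(days_per_year)
  if (is.na(days_per_year) || days_per_year < 4L)
    stop("'days_per_year' must be a positive integer (>= 4)", call. = FALSE)
  if (!is.numeric(par_conversion) || par_conversion <= 0)
    stop("'par_conversion' must be positive", call. = FALSE)
  structure(
    list(eccentricity = eccentricity,
         obliquity = obliquity,
         lon_perihelion = lon_perihelion %% 360,
         solar_constant = solar_constant,
         days_per_year = days_per_year,
         par_conversion = par_conversion),
    class = "orbit_config")
}

#' @export
print.orbit_config <- function(x, ...) {
  cat("<orbit_config>\n")
  cat(sprintf("  eccentricity      : %.5f\n", x$eccentricity))
  cat(sprintf("  obliquity         : %.3f deg\n", x$obliquity))
  cat(sprintf("  lon. of perihelion: %.2f deg\n", x$lon_perihelion))
  cat(sprintf("  solar constant    : %.1f W m-2\n", x$solar_constant))
  cat(sprintf("  days per year     : %d\n", x$days_per_year))
  cat(sprintf("  PAR conversion    : %.4f umol J-1\n", x$par_conversion))
  invisible(x)
}

# Calendar anchor: vernal equinox day-of-year for a January-1 calendar.
.vernal_equinox_day <- 80

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

.check_day <- function(day, orbit) {
  if (any(!is.finite(day)) || any(day < 1) || any(day > orbit$days_per_year))
    stop(sprintf("'day' must lie in [1, %d]", orbit$days_per_year),
         call. = FALSE)
  invisible(day)
}
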