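# The three limitation functions of the calcification model: light saturation,
# dark-day tolerance, and the SST envelope, plus PAR unit helpers.

#' Light-limitation parameters
#'
#' Parameters of the light side of the model. Defaults reflect a clear-water
#' reef at 15 m depth (k_par = 0.05 m^-1, so k_par*z = 0.75 and a 92 m photic
#' zone), a saturating intensity E_k = 50 umol m^-2 s^-1, a dark-day threshold
#' E_lim = 105 umol m^-2 s^-1 and a darkness tolerance of 26 days per year.
#'
#' @param E_k Saturating light intensity of the tanh photosynthesis-irradiance
#'   response, umol m^-2 s^-1 (> 0).
#' @param E_lim Dark-day threshold: days whose surface PAR stays strictly below
#'   this flux count as dark, umol m^-2 s^-1 (>= 0).
#' @param k_par Diffuse attenuation coefficient of PAR, m^-1 (> 0).
#' @param z Habitat depth, m (>= 0).
#' @param tolerance_days Maximum tolerable number of dark days per year
#'   (integer in `[0, 365]`), or `NULL` to disable the dark-day rule.
#' @return An object of class `light_params`.
#' @export
light_params <- function(E_k = 50, E_lim = 105, k_par = 0.05, z = 15,
                         tolerance_days = 26) {
  if (!is.numeric(E_k) || E_k <= 0) stop("'E_k' must be > 0", call. = FALSE)
  if (!is.numeric(E_lim) || E_lim < 0) stop("'E_lim' must be >= 0", call. = FALSE)
  if (!is.numeric(k_par) || k_par <= 0) stop("'k_par' must be > 0", call. = FALSE)
  if (!is.numeric(z) || z < 0) stop("'z' must be >= 0", call. = FALSE)
  if (!is.null(tolerance_days)) {
    tolerance_days <- as.integer(tolerance_days)
    if (is.na(tolerance_days) || tolerance_days < 0 || tolerance_days > 365)
      stop("'tolerance_days' must be an integer in [0, 365] or NULL",
           call. = FALSE)
  }
  structure(list(E_k = E_k, E_lim = E_lim, k_par = k_par, z = z,
                 tolerance_days = tolerance_days),
            class = "light_params")
}

#' @export
print.light_params <- function(x, ...) {
  cat("<light_params>\n")
  cat(sprintf("  E_k   : %g umol m-2 s-1\n", x$E_k))
  cat(sprintf("  E_lim : %g umol m-2 s-1\n", x$E_lim))
  cat(sprintf("  k_par : %g m-1   z: %g m   (k_par*z = %g, photic depth %g m)\n",
              x$k_par, x$z, x$k_par * x$z, photic_depth(x$k_par)))
  cat(sprintf("  dark-day tolerance : %s\n",
              if (is.null(x$tolerance_days)) "disabled"
              else paste(x$tolerance_days, "days")))
  invisible(x)
}

#' Temperature envelope for calcification
#'
#' Coldest-month and warmest-month SST bounds between which calcification is
#' allowed. The 16-36 degC default spans the extremes reported across reef
#' coral species, a deliberately permissive envelope.
#'
#' @param T_min Minimum tolerated coldest-month SST, degC.
#' @param T_max Maximum tolerated warmest-month SST, degC.
#' @return An object of class `temperature_envelope`.
#' @export
temperature_envelope <- function(T_min = 16, T_max = 36) {
  if (!is.numeric(T_min) || !is.numeric(T_max) || T_min >= T_max)
    stop("'T_min' must be smaller than 'T_max'", call. = FALSE)
  structure(list(T_min = T_min, T_max = T_max), class = "temperature_envelope")
}

#' Lambert-Beer attenuation of PAR to depth
#'
#' \deqn{E_z = E_{surface} e^{-k_{par} z}}
#'
#' @param E_surface Surface PAR flux, umol m^-2 s^-1 (>= 0).
#' @param k_par Attenuation coefficient, m^-1 (> 0).
#' @param z Depth, m (>= 0).
#' @return Attenuated PAR flux at depth `z`.
#' @examples
#' attenuate(100, 0.05, 15)       # k_par*z = 0.75
#' attenuate(100, 0.05, photic_depth(0.05))  # the 1% light level
#' @export
attenuate <- function(E_surface, k_par, z) {
  if (any(E_surface < 0)) stop("'E_surface' must be >= 0", call. = FALSE)
  if (any(k_par <= 0)) stop("'k_par' must be > 0", call. = FALSE)
  if (any(z < 0)) stop("'z' must be >= 0", call. = FALSE)
  E_surface * exp(-k_par * z)
}

#' Photic depth (1% light level)
#'
#' Depth at which PAR has fallen to 1% of its surface value under Lambert-Beer
#' attenuation: `4.6 / k_par` (since exp(-4.6) ~ 0.01).
#'
#' @param k_par Attenuation coefficient, m^-1 (> 0).
#' @return Photic depth in metres.
#' @examples
#' photic_depth(0.05)  # 92 m, clear oceanic water
#' photic_depth(0.20)  # 23 m, turbid coastal water
#' @export
photic_depth <- function(k_par) {
  if (any(k_par <= 0)) stop("'k_par' must be > 0", call. = FALSE)
  4.6 / k_par
}

#' Light-saturation limitation factor
#'
#' Hyperbolic-tangent photosynthesis-irradiance response:
#' \eqn{f_{light} = \tanh(E_z / E_k)}, in `[0, 1)`, monotone in `E_z`.
#'
#' @param E_z Available PAR at habitat depth, umol m^-2 s^-1 (>= 0).
#' @param E_k Saturating light intensity, umol m^-2 s^-1 (> 0).
#' @return Dimensionless limitation factor.
#' @export
f_light <- function(E_z, E_k) {
  if (any(E_k <= 0)) stop("'E_k' must be > 0", call. = FALSE)
  if (any(E_z < 0)) stop("'E_z' must be >= 0", call. = FALSE)
  tanh(E_z / E_k)
}

#' Count dark days in a yearly surface PAR series
#'
#' A day is "dark" when its surface PAR stays strictly below `E_lim`. Counting
#' uses surface light, never light at depth, so that darkness cannot be
#' escaped by an upward shift of the population.
#'
#' @param daily_surface_par Numeric vector of daily surface PAR values for one
#'   latitude, of length `n_days`.
#' @param E_lim Dark-day threshold, umol m^-2 s^-1.
#' @param n_days Expected series length (days per year), default 365.
#' @return Integer count in `[0, n_days]`.
#' @export
count_dark_days <- function(daily_surface_par, E_lim, n_days = 365L) {
  if (length(daily_surface_par) != n_days)
    stop(sprintf("'daily_surface_par' must have length %d (got %d)",
                 n_days, length(daily_surface_par)), call. = FALSE)
  if (any(daily_surface_par < 0))
    stop("'daily_surface_par' must be non-negative", call. = FALSE)
  sum(daily_surface_par < E_lim)
}

#' Dark-day tolerance limitation factor
#'
#' Step function: 0 when the yearly dark-day count exceeds the tolerance,
#' else 1. Equality (count == tolerance) is tolerated. A `NULL` tolerance
#' disables the rule (always 1).
#'
#' @param n_dark Yearly dark-day count (non-negative integer, vectorized).
#' @param tolerance_days Tolerated dark days per year, or `NULL`.
#' @return 0 or 1 (numeric).
#' @export
f_darkdays <- function(n_dark, tolerance_days) {
  if (any(n_dark < 0)) stop("'n_dark' must be >= 0", call. = FALSE)
  if (is.null(tolerance_days)) return(rep(1, length(n_dark)))
  if (any(tolerance_days < 0)) stop("'tolerance_days' must be >= 0", call. = FALSE)
  as.numeric(!(n_dark > tolerance_days))
}

#' Temperature-envelope limitation factor
#'
#' Step function of the coldest- and warmest-month SST: 1 iff
#' `T_min <= T_winter` and `T_summer <= T_max`, else 0. An annual gate: all
#' days of a year at one latitude are gated uniformly.
#'
#' @param T_winter Coldest-month mean SST, degC (vectorized).
#' @param T_summer Warmest-month mean SST, degC.
#' @param envelope A [temperature_envelope()].
#' @return 0 or 1 (numeric).
#' @export
f_temp <- function(T_winter, T_summer, envelope = temperature_envelope()) {
  if (any(T_winter > T_summer))
    stop("'T_winter' must not exceed 'T_summer'", call. = FALSE)
  as.numeric(T_winter >= envelope$T_min & T_summer <= envelope$T_max)
}

#' Convert a sustained PAR flux to a daily photon dose
#'
#' @param flux PAR photon flux, umol m^-2 s^-1.
#' @param hours Hours per day over which the flux is sustained (default 12).
#' @return Daily dose in mol photons m^-2 day^-1.
#' @examples
#' par_daily_dose(300)        # ~13 mol m-2 day-1 for a 12-h day
#' @export
par_daily_dose <- function(flux, hours = 12) {
  flux * hours * 3600 / 1e6
}

#' Convert a daily photon dose to a sustained PAR flux
#'
#' @param dose Daily dose, mol photons m^-2 day^-1.
#' @param hours Hours per day over which the dose is delivered (default 12).
#' @return PAR photon flux in umol m^-2 s^-1.
#' @examples
#' par_flux_from_dose(1.5)    # ~35 umol m-2 s-1 for a 12-h day
#' @export
par_flux_from_dose <- function(dose, hours = 12) {
  dose * 1e6 / (hours * 3600)
}
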