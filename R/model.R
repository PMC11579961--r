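# The calcification box model: daily and yearly rates per latitude, profile
# normalization, parameter sweeps, and the E_lim/tolerance cutoff fit.

#' Model configuration
#'
#' Bundles all model parameters: the unlimited calcification potential `G_max`
#' (arbitrary units; yearly output is normalized to a percentage anyway), the
#' light parameters, the temperature envelope, the orbit, and the latitude
#' grid.
#'
#' @param G_max Unlimited ("100%") calcification potential, > 0.
#' @param light A [light_params()].
#' @param envelope A [temperature_envelope()].
#' @param orbit An [orbit_config()].
#' @param grid_step Latitude grid step in degrees; the grid covers 0-90
#'   inclusive.
#' @param light_label_threshold Percentage of the profile maximum below which
#'   a latitude whose gates are all open is labelled light-limited (default
#'   99).
#' @return An object of class `model_config`.
#' @export
model_config <- function(G_max = 1, light = light_params(),
                         envelope = temperature_envelope(),
                         orbit = orbit_config(), grid_step = 1,
                         light_label_threshold = 99) {
  if (!is.numeric(G_max) || G_max <= 0) stop("'G_max' must be > 0", call. = FALSE)
  stopifnot(inherits(light, "light_params"),
            inherits(envelope, "temperature_envelope"),
            inherits(orbit, "orbit_config"))
  if (!is.numeric(grid_step) || grid_step <= 0 || 90 %% grid_step != 0)
    stop("'grid_step' must be a positive divisor of 90", call. = FALSE)
  structure(list(G_max = G_max, light = light, envelope = envelope,
                 orbit = orbit, grid_step = grid_step,
                 light_label_threshold = light_label_threshold),
            class = "model_config")
}

# Coldest/warmest month SST at arbitrary latitudes, linearly interpolated
# within the scenario grid; refuses latitudes outside it.
scenario_at <- function(scenario, latitude) {
  rng <- range(scenario$latitude)
  if (any(latitude < rng[1]) || any(latitude > rng[2]))
    stop(sprintf("latitude outside scenario grid [%g, %g]", rng[1], rng[2]),
         call. = FALSE)
  list(
    coldest = stats::approx(scenario$latitude, scenario$coldest_month_sst,
                            xout = latitude)$y,
    warmest = stats::approx(scenario$latitude, scenario$warmest_month_sst,
                            xout = latitude)$y)
}

#' Daily calcification rate at one latitude
#'
#' Evaluates \eqn{G = G_{max} \tanh(E_z/E_k) f_{darkdays} f_{temp}} for the
#' requested days, where \eqn{E_z} is the surface PAR attenuated to habitat
#' depth. The dark-day factor depends on the full year of surface PAR at the
#' latitude and the temperature factor on the scenario's monthly extremes, so
#' both gate all days of the year uniformly.
#'
#' @param latitude Latitude in degrees, within the scenario grid.
#' @param day Day(s) of year.
#' @param config A [model_config()].
#' @param scenario A [temperature_scenario()].
#' @return Numeric vector of daily calcification rates in `[0, G_max]`.
#' @examples
#' cfg <- model_config()
#' daily_calcification(30, c(80, 172, 355), cfg, scenario_preset("eocene-x6-like"))
#' @export
daily_calcification <- function(latitude, day, config, scenario) {
  stopifnot(inherits(config, "model_config"),
            inherits(scenario, "temperature_scenario"))
  .check_day(day, config$orbit)
  lp <- config$light
  es_year <- surface_par_series(latitude, config$orbit)
  nd <- count_dark_days(es_year, lp$E_lim, config$orbit$days_per_year)
  sst <- scenario_at(scenario, latitude)
  ft <- f_temp(sst$coldest, sst$warmest, config$envelope)
  fd <- f_darkdays(nd, lp$tolerance_days)
  ez <- attenuate(es_year[day], lp$k_par, lp$z)
  config$G_max * f_light(ez, lp$E_k) * fd * ft
}

#' Yearly latitudinal calcification profile
#'
#' Sums daily calcification over the year at every grid latitude and
#' normalizes to the profile maximum. Each latitude is annotated with its
#' yearly dark-day count and the factor limiting it: `"cold"`/`"heat"` when
#' the temperature envelope gates, `"dark_days"` when the dark-day tolerance
#' gates, `"multiple"` when more than one gate closes, `"light"` when all
#' gates are open but the yearly percentage falls below
#' `light_label_threshold`, else `"none"`.
#'
#' @param config A [model_config()].
#' @param scenario A [temperature_scenario()].
#' @return A data frame of class `coral_profile` with columns `latitude`,
#'   `yearly_G`, `yearly_pct`, `dark_days`, `limiting_factor`; the resolved
#'   configuration is attached as attribute `config`.
#' @examples
#' prof <- yearly_profile(model_config(), scenario_preset("eocene-x6-like"))
#' poleward_cutoff(prof)
#' @export
yearly_profile <- function(config, scenario) {
  stopifnot(inherits(config, "model_config"),
            inherits(scenario, "temperature_scenario"))
  lp <- config$light
  lats <- seq(0, 90, by = config$grid_step)
  E <- surface_par_grid(lats, config$orbit)
  dark <- as.integer(rowSums(E < lp$E_lim))
  fd <- f_darkdays(dark, lp$tolerance_days)
  sst <- scenario_at(scenario, lats)
  ft <- f_temp(sst$coldest, sst$warmest, config$envelope)
  light_sum <- rowSums(f_light(attenuate(E, lp$k_par, lp$z), lp$E_k))
  yearly_G <- config$G_max * light_sum * fd * ft
  gmax <- max(yearly_G)
  yearly_pct <- if (gmax > 0) 100 * yearly_G / gmax else rep(0, length(lats))

  cold_gate <- sst$coldest < config$envelope$T_min
  heat_gate <- sst$warmest > config$envelope$T_max
  dark_gate <- fd == 0
  n_gate <- cold_gate + heat_gate + dark_gate
  limiting <- ifelse(n_gate > 1, "multiple",
              ifelse(cold_gate, "cold",
              ifelse(heat_gate, "heat",
              ifelse(dark_gate, "dark_days",
              ifelse(yearly_pct < config$light_label_threshold,
                     "light", "none")))))
  structure(
    data.frame(latitude = lats, yearly_G = yearly_G, yearly_pct = yearly_pct,
               dark_days = dark, limiting_factor = limiting),
    config = config, scenario_name = attr(scenario, "name"),
    class = c("coral_profile", "data.frame"))
}

#' Poleward cutoff latitude of a profile
#'
#' The highest latitude with nonzero yearly calcification; `NA` if no
#' latitude calcifies.
#'
#' @param profile A `coral_profile` from [yearly_profile()].
#' @return Latitude in degrees, or `NA_real_`.
#' @export
poleward_cutoff <- function(profile) {
  stopifnot(inherits(profile, "coral_profile"))
  i <- which(profile$yearly_G > 0)
  if (!length(i)) return(NA_real_)
  max(profile$latitude[i])
}

#' Parameter sweep over the light parameters
#'
#' Runs [yearly_profile()] over the Cartesian product of the supplied axes for
#' the saturating intensity `E_k`, the optical thickness `kpar_z` (the product
#' k_par * z, applied at the configured depth), the dark-day threshold
#' `E_lim`, and the darkness tolerance. Rows are ordered lexicographically
#' (`E_k` most significant, then `kpar_z`, `E_lim`, `tolerance_days`).
#'
#' @param config A [model_config()]; its light parameters supply any axis not
#'   swept.
#' @param scenario A [temperature_scenario()].
#' @param E_k,kpar_z,E_lim Numeric axes (defaults: the configured single
#'   values).
#' @param tolerance_days Integer axis; may contain `NA` for "rule disabled".
#' @param keep_profiles If `TRUE` (default) the full profile of every
#'   combination is attached as attribute `profiles`.
#' @return A data frame of class `coral_sweep` with the four parameter columns
#'   and the poleward `cutoff` latitude per combination (`NA` when nothing
#'   calcifies).
#' @examples
#' sw <- calc_sweep(model_config(), scenario_preset("eocene-x6-like"),
#'                  E_k = c(50, 100), kpar_z = c(0.75, 1.5))
#' sw$cutoff
#' @export
calc_sweep <- function(config, scenario,
                       E_k = config$light$E_k,
                       kpar_z = config$light$k_par * config$light$z,
                       E_lim = config$light$E_lim,
                       tolerance_days = config$light$tolerance_days,
                       keep_profiles = TRUE) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(tolerance_days)) tolerance_days <- NA_integer_
  axes <- list(E_k = E_k, kpar_z = kpar_z, E_lim = E_lim,
               tolerance_days = tolerance_days)
  for (nm in names(axes))
    if (!length(axes[[nm]]))
      stop(sprintf("sweep axis '%s' is empty", nm), call. = FALSE)
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)[, names(axes)]
  grid <- grid[order(grid$E_k, grid$kpar_z, grid$E_lim, grid$tolerance_days,
                     na.last = FALSE), , drop = FALSE]
  rownames(grid) <- NULL

  profiles <- vector("list", nrow(grid))
  cutoff <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lp <- config$light
    cfg_i <- config
    cfg_i$light <- light_params(
      E_k = grid$E_k[i], E_lim = grid$E_lim[i],
      k_par = grid$kpar_z[i] / lp$z, z = lp$z,
      tolerance_days = if (is.na(grid$tolerance_days[i])) NULL
                       else grid$tolerance_days[i])
    prof <- yearly_profile(cfg_i, scenario)
    profiles[[i]] <- prof
    cutoff[i] <- poleward_cutoff(prof)
  }
  grid$cutoff <- cutoff
  structure(grid,
            profiles = if (keep_profiles) profiles else NULL,
            class = c("coral_sweep", "data.frame"))
}

#' Fit the dark-day threshold and tolerance to a target poleward cutoff
#'
#' Searches the `E_lim` grid (ascending) for the smallest dark-day threshold
#' for which some tolerance in `tolerance_range` excludes calcification (via
#' the dark-day rule alone) at every latitude poleward of `target_cutoff`
#' while permitting it at `target_cutoff` and all lower latitudes, under an
#' unlimiting-temperature scenario. Dark days are counted on surface PAR from
#' the configured orbit. Also reports the full interval of feasible tolerances
#' at the fitted threshold.
#'
#' @param config A [model_config()] (supplies the orbit and grid step).
#' @param target_cutoff Target poleward cutoff latitude in degrees, on the
#'   grid.
#' @param E_lim_grid Candidate thresholds, umol m^-2 s^-1 (default 20-400 in
#'   steps of 5).
#' @param tolerance_range Candidate integer tolerances (default 1-365 days).
#' @return An object of class `coral_fit`: a list with elements `feasible`,
#'   `E_lim` (minimal feasible threshold, `NA` if none), `tolerance`
#'   (two-element feasible interval), `target_cutoff`, `dark_days` (matrix of
#'   counts, latitude x threshold) and `par_conversion` (the factor used).
#'   Infeasibility is reported in the object, not as an error.
#' @examples
#' \donttest{
#' fit <- fit_light_cutoff(model_config(), target_cutoff = 50)
#' fit$E_lim      # minimal threshold
#' fit$tolerance  # feasible tolerance interval
#' }
#' @export
fit_light_cutoff <- function(config, target_cutoff = 50,
                             E_lim_grid = seq(20, 400, by = 5),
                             tolerance_range = 1:365) {
  stopifnot(inherits(config, "model_config"))
  lats <- seq(0, 90, by = config$grid_step)
  if (!target_cutoff %in% lats || target_cutoff >= 90)
    stop("'target_cutoff' must be a grid latitude below 90", call. = FALSE)
  if (!length(E_lim_grid) || !length(tolerance_range))
    stop("'E_lim_grid' and 'tolerance_range' must be non-empty", call. = FALSE)
  E_lim_grid <- sort(E_lim_grid)
  tol_min <- min(tolerance_range); tol_max <- max(tolerance_range)

  E <- surface_par_grid(lats, config$orbit)
  dark <- vapply(E_lim_grid, function(el) rowSums(E < el),
                 numeric(length(lats)))
  dimnames(dark) <- list(latitude = lats, E_lim = E_lim_grid)

  below <- lats <= target_cutoff
  result <- list(feasible = FALSE, E_lim = NA_real_,
                 tolerance = c(NA_integer_, NA_integer_),
                 target_cutoff = target_cutoff, E_lim_grid = E_lim_grid,
                 tolerance_range = c(tol_min, tol_max), dark_days = dark,
                 par_conversion = config$orbit$par_conversion)
  for (j in seq_along(E_lim_grid)) {
    lo <- max(max(dark[below, j]), tol_min)   # permit all lats <= target
    hi <- min(min(dark[!below, j]) - 1, tol_max)  # exclude all lats > target
    if (lo <= hi) {
      result$feasible <- TRUE
      result$E_lim <- E_lim_grid[j]
      result$tolerance <- c(as.integer(lo), as.integer(hi))
      break
    }
  }
  structure(result, class = "coral_fit")
}

#' @export
print.coral_fit <- function(x, ...) {
  cat("<coral_fit>\n")
  cat(sprintf("  target poleward cutoff : %g deg\n", x$target_cutoff))
  cat(sprintf("  E_lim grid             : %g-%g umol m-2 s-1 (%d values)\n",
              min(x$E_lim_grid), max(x$E_lim_grid), length(x$E_lim_grid)))
  cat(sprintf("  tolerance range        : %d-%d days\n",
              x$tolerance_range[1], x$tolerance_range[2]))
  cat(sprintf("  PAR conversion factor  : %.4f umol J-1\n", x$par_conversion))
  if (x$feasible) {
    cat(sprintf("  minimal E_lim          : %g umol m-2 s-1\n", x$E_lim))
    cat(sprintf("  feasible tolerances    : %d-%d days\n",
                x$tolerance[1], x$tolerance[2]))
  } else {
    cat("  no feasible combination\n")
  }
  invisible(x)
}
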