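# Temperature scenarios: synthetic meridional SST gradients, bundled presets,
# a CSV reader/writer, and the 16 degC crossing diagnostic.

#' Temperature scenario by latitude
#'
#' A per-latitude pair of coldest-month and warmest-month mean SST curves on an
#' ascending 0-90 degree grid (unsigned latitude; hemispheres are treated
#' symmetrically).
#'
#' @param latitudes Ascending latitudes in degrees, within `[0, 90]`.
#' @param coldest_month_sst Coldest-month mean SST per latitude, degC.
#' @param warmest_month_sst Warmest-month mean SST per latitude, degC.
#' @param name Scenario label.
#' @return A data frame of class `temperature_scenario` with columns
#'   `latitude`, `coldest_month_sst`, `warmest_month_sst` and a `name`
#'   attribute.
#' @export
temperature_scenario <- function(latitudes, coldest_month_sst,
                                 warmest_month_sst, name = "scenario") {
  n <- length(latitudes)
  if (length(coldest_month_sst) != n || length(warmest_month_sst) != n)
    stop("latitude and SST vectors must have equal length", call. = FALSE)
  if (any(latitudes < 0) || any(latitudes > 90))
    stop("'latitudes' must lie in [0, 90]", call. = FALSE)
  if (is.unsorted(latitudes, strictly = TRUE))
    stop("'latitudes' must be strictly ascending", call. = FALSE)
  if (any(warmest_month_sst < coldest_month_sst))
    stop("'warmest_month_sst' must be >= 'coldest_month_sst' at every latitude",
         call. = FALSE)
  structure(
    data.frame(latitude = latitudes,
               coldest_month_sst = coldest_month_sst,
               warmest_month_sst = warmest_month_sst),
    name = name, class = c("temperature_scenario", "data.frame"))
}

#' @export
print.temperature_scenario <- function(x, ...) {
  cat(sprintf("<temperature_scenario> '%s': %d latitudes (%g-%g deg)\n",
              attr(x, "name"), nrow(x), min(x$latitude), max(x$latitude)))
  cat(sprintf("  coldest month: %.1f degC (equatorward end) to %.1f degC (poleward end)\n",
              x$coldest_month_sst[1], x$coldest_month_sst[nrow(x)]))
  cat(sprintf("  warmest month: %.1f degC to %.1f degC\n",
              x$warmest_month_sst[1], x$warmest_month_sst[nrow(x)]))
  invisible(x)
}

#' Synthetic meridional SST gradient specification
#'
#' Endpoint temperatures and a shape exponent for a smooth poleward-declining
#' gradient \eqn{T(\phi) = T_{pole} + (T_{eq} - T_{pole}) \cos^p \phi},
#' applied separately to the coldest- and warmest-month curves.
#'
#' @param T_eq_cold,T_pole_cold Coldest-month SST at 0 and 90 degrees, degC.
#' @param T_eq_warm,T_pole_warm Warmest-month SST at 0 and 90 degrees, degC.
#' @param shape_exponent Gradient steepness exponent p > 0 (2 is a good
#'   emulation of zonal-mean climatologies).
#' @return An object of class `synth_gradient_spec`.
#' @export
synth_gradient_spec <- function(T_eq_cold, T_pole_cold,
                                T_eq_warm, T_pole_warm,
                                shape_exponent = 2) {
  if (T_eq_cold < T_pole_cold || T_eq_warm < T_pole_warm)
    stop("equator temperatures must be >= pole temperatures", call. = FALSE)
  if (T_eq_warm < T_eq_cold || T_pole_warm < T_pole_cold)
    stop("warmest-month endpoints must be >= coldest-month endpoints",
         call. = FALSE)
  if (!is.numeric(shape_exponent) || shape_exponent <= 0)
    stop("'shape_exponent' must be > 0", call. = FALSE)
  structure(list(T_eq_cold = T_eq_cold, T_pole_cold = T_pole_cold,
                 T_eq_warm = T_eq_warm, T_pole_warm = T_pole_warm,
                 shape_exponent = shape_exponent),
            class = "synth_gradient_spec")
}

#' Generate a synthetic temperature scenario
#'
#' Evaluates the cos^p gradient of a [synth_gradient_spec()] on the model
#' latitude grid. Endpoints are exact and both curves are monotone
#' non-increasing with latitude.
#'
#' @param spec A [synth_gradient_spec()].
#' @param grid_step Latitude grid step in degrees (default 1).
#' @param name Scenario label.
#' @return A [temperature_scenario()].
#' @examples
#' sc <- synth_scenario(synth_gradient_spec(28, -1.8, 30, 0.5))
#' crossing_latitude(sc, 16)
#' @export
synth_scenario <- function(spec, grid_step = 1, name = "synthetic") {
  stopifnot(inherits(spec, "synth_gradient_spec"))
  lat <- seq(0, 90, by = grid_step)
  shape <- cos(deg2rad(lat))^spec$shape_exponent
  shape[length(shape)] <- 0  # exact pole endpoint (cos 90 is 0 up to rounding)
  temperature_scenario(
    lat,
    spec$T_pole_cold + (spec$T_eq_cold - spec$T_pole_cold) * shape,
    spec$T_pole_warm + (spec$T_eq_warm - spec$T_pole_warm) * shape,
    name = name)
}

# Preset gradient parameters. Endpoints solved (cos^2 shape) so the x6-like
# coldest-month curve crosses 16 degC at 54 deg and the x9-like at 71 deg,
# with warm-limit (36 degC) crossings near 35 and 53 deg; emulations of
# zonal-mean hothouse and modern climatologies, not climate-model output.
.scenario_presets <- list(
  "modern-like"    = list(27.0, -1.8, 29.5,  0.5, 2),
  "eocene-x3-like" = list(31.0,  3.0, 35.0, 10.0, 2),
  "eocene-x6-like" = list(33.0,  6.7, 41.0, 25.4, 2),
  "eocene-x9-like" = list(38.0, 13.2, 44.0, 31.3, 2)
)

#' Bundled synthetic scenario presets
#'
#' Four smooth zonal-mean SST gradient emulations: `"modern-like"` (tropical
#' coldest month ~27 degC, sub-zero pole), and three progressively warmer
#' hothouse gradients `"eocene-x3-like"`, `"eocene-x6-like"` and
#' `"eocene-x9-like"`. The x6-like coldest-month curve first drops below
#' 16 degC at 54 degrees latitude and the x9-like at 71 degrees; the x6-like
#' and x9-like warmest-month curves exceed 36 degC equatorward of 35 and 53
#' degrees respectively. The presets are synthetic emulations, not climate
#' model or observational data.
#'
#' @param name Preset name.
#' @param grid_step Latitude grid step in degrees.
#' @return A [temperature_scenario()].
#' @examples
#' crossing_latitude(scenario_preset("eocene-x6-like"), 16)  # 54
#' @export
scenario_preset <- function(name = c("modern-like", "eocene-x3-like",
                                     "eocene-x6-like", "eocene-x9-like"),
                            grid_step = 1) {
  name <- match.arg(name)
  p <- .scenario_presets[[name]]
  synth_scenario(synth_gradient_spec(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]]),
                 grid_step = grid_step, name = name)
}

#' Latitude at which the coldest month crosses a temperature threshold
#'
#' The lowest grid latitude at which the coldest-month SST falls strictly
#' below `threshold`; `NA` if no grid latitude does.
#'
#' @param scenario A [temperature_scenario()].
#' @param threshold Temperature threshold, degC (default 16, the envelope
#'   minimum).
#' @return Latitude in degrees, or `NA_real_`.
#' @export
crossing_latitude <- function(scenario, threshold = 16) {
  stopifnot(inherits(scenario, "temperature_scenario"))
  i <- which(scenario$coldest_month_sst < threshold)
  if (!length(i)) return(NA_real_)
  scenario$latitude[min(i)]
}

#' Read a temperature scenario from file
#'
#' Reads a per-latitude scenario from CSV (columns `latitude`,
#' `coldest_month_sst`, `warmest_month_sst`; header required; lines starting
#' with `#` ignored). Southern-hemisphere rows (negative latitudes) are folded
#' onto unsigned latitude by averaging with their northern counterparts, and
#' the curves are linearly interpolated to the 0-90 degree model grid. The
#' input must span the full grid: extrapolation is refused.
#'
#' @param path File path.
#' @param format Only `"csv"` is supported in this build; `"netcdf"` raises an
#'   informative error.
#' @param lat_col,cold_col,warm_col Column names in the file.
#' @param grid_step Model grid step in degrees.
#' @param name Scenario label (defaults to the file name).
#' @return A [temperature_scenario()].
#' @seealso [write_scenario()]
#' @export
read_scenario <- function(path, format = c("csv", "netcdf"),
                          lat_col = "latitude",
                          cold_col = "coldest_month_sst",
                          warm_col = "warmest_month_sst",
                          grid_step = 1, name = NULL) {
  format <- match.arg(format)
  if (format == "netcdf")
    stop("NetCDF scenario files are not supported by this build; ",
         "export the zonal means to CSV (columns latitude, ",
         "coldest_month_sst, warmest_month_sst) instead", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("scenario file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  for (col in c(lat_col, cold_col, warm_col))
    if (!col %in% names(df))
      stop(sprintf("scenario file '%s' lacks required column '%s'", path, col),
           call. = FALSE)
  lat <- abs(df[[lat_col]])
  fold <- function(v) {
    agg <- stats::aggregate(v, list(lat = lat), mean)
    agg[order(agg$lat), ]
  }
  cold <- fold(df[[cold_col]]); warm <- fold(df[[warm_col]])
  grid <- seq(0, 90, by = grid_step)
  if (min(cold$lat) > 0 || max(cold$lat) < 90)
    stop(sprintf(paste0("scenario latitudes span [%g, %g] but the model grid ",
                        "needs [0, 90]; extrapolation is refused"),
                 min(cold$lat), max(cold$lat)), call. = FALSE)
  interp <- function(a) stats::approx(a$lat, a$x, xout = grid, ties = mean)$y
  temperature_scenario(grid, interp(cold), interp(warm),
                       name = if (is.null(name)) basename(path) else name)
}

#' Write a temperature scenario to CSV
#'
#' Writes the three scenario columns in full double precision (so a
#' [read_scenario()] round trip reproduces the values exactly), preceded by
#' `#`-prefixed provenance comments.
#'
#' @param scenario A [temperature_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "temperature_scenario"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature scenario: %s", attr(scenario, "name")),
               "# columns: latitude [deg], coldest/warmest month mean SST [degC]"),
             con)
  writeLines("latitude,coldest_month_sst,warmest_month_sst", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", scenario$latitude,
                     scenario$coldest_month_sst, scenario$warmest_month_sst),
             con)
  invisible(path)
}
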