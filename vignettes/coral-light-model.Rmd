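---
title: "A latitude-resolved light and temperature limitation model of coral calcification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latitude-resolved light and temperature limitation model of coral calcification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralight)
```

## The question the model addresses

Shallow-water tropical corals calcify only where their photosymbionts receive
enough light and where sea-surface temperature stays within a tolerable
envelope year-round. Under modern climate, the coldest-month 16 degC isotherm
sits near 30-35 degrees latitude and temperature is what terminates the reef
belt. Under hothouse climates, water warmer than 16 degC reached far poleward
of 50 degrees, yet fossil reefs are still absent beyond about 50 degrees
paleolatitude. This package implements a box model that separates the two
controls: it computes, per degree of latitude, a yearly calcification
potential limited by (i) the saturation response to available light, (ii) a
tolerance to "dark days", and (iii) the SST envelope, so that one can ask
which control caps the poleward edge under any meridional temperature
gradient.

## Model structure

The daily calcification rate at latitude $\phi$ and day $d$ is

$$G = G_{max}\,\tanh\!\left(\frac{E_z}{E_k}\right)\, f_{darkdays}\, f_{temp},$$

with the three limitation terms defined as follows.

**Light saturation.** Surface PAR is attenuated to habitat depth $z$ by the
Lambert-Beer law, $E_z = E_{surface}\,e^{-k_{par} z}$; the dimensionless
optical thickness $k_{par} z$ is what matters, and the photic (1%-light)
depth is $4.6/k_{par}$. The saturation response $\tanh(E_z/E_k)$ is the
standard hyperbolic-tangent photosynthesis-irradiance curve; the saturating
intensity $E_k$ (umol m$^{-2}$ s$^{-1}$) varies among species, roughly 50-300
in the literature. Defaults: $E_k = 50$, $k_{par} = 0.05$ m$^{-1}$, $z = 15$
m (so $k_{par}z = 0.75$, a clear-water reef above a 92 m photic zone).

**Dark days.** A day is "dark" when the *surface* PAR (never the attenuated
value, so that the darkness cannot be escaped by moving up the water column)
stays strictly below a threshold $E_{lim}$. If the yearly count of dark days
exceeds an integer tolerance, calcification is zeroed for that latitude; a
count equal to the tolerance is tolerated. Defaults: $E_{lim} = 105$ umol
m$^{-2}$ s$^{-1}$ with a 26-day tolerance — the fitted pair discussed below.

**Temperature.** Calcification requires the coldest-month mean SST to be at
least 16 degC and the warmest-month mean at most 36 degC, a deliberately
permissive envelope spanning reported species extremes; the gate applies
uniformly to the whole year at a latitude.

Yearly calcification is the plain sum of daily $G$ over the 365-day year, and
profiles are reported as percent of the maximum over latitudes for the same
scenario and configuration.

## Solar forcing

Daily surface light is computed from orbital geometry, with no external
forcing data. For each day the true solar longitude follows from the mean
longitude and an equation-of-centre expansion (third order in eccentricity),
anchored so the vernal equinox falls on calendar day 80; declination,
sunset hour angle $\omega_s = \arccos(-\tan\phi\tan\delta)$ (clamped for
polar day/night), day length $24\,\omega_s/\pi$, and the 24-hour-mean
top-of-atmosphere irradiance (including the Sun-Earth distance factor) follow
in closed form. The modern orbit is assumed (eccentricity 0.0167, obliquity
23.44 degrees, perihelion longitude 282.95 degrees, solar constant 1361 W
m$^{-2}$); equinoxes and solstices are located from the orbital longitude, so
the engine remains valid for other orbital configurations.

**From irradiance to E_surface.** $E_{surface}$ is defined here as the
*daylight-hours mean* PAR photon flux: the daily top-of-atmosphere insolation
converted to photons and spread over the hours with daylight,
$E_{surface} = \bar W \cdot c_{PAR} \cdot 24/L$ with $L$ the day length in
hours, and zero on polar-night days. Two considerations fix this choice over
a 24-hour mean. First, light thresholds in the reef literature are quoted as
fluxes sustained over the photoperiod — e.g. 300 umol m$^{-2}$ s$^{-1}$ "for
a 12-h day" equals a 13 mol m$^{-2}$ day$^{-1}$ dose, and 1.5 mol m$^{-2}$
day$^{-1}$ equals 35 umol m$^{-2}$ s$^{-1}$ (see `par_daily_dose()` /
`par_flux_from_dose()`) — so comparing a daylight-mean flux against
$E_{lim}$ keeps the threshold on its native scale. Second, under the 24-hour
mean no conversion factor allows the dark-day fit at a 50-degree cutoff
(below) to land simultaneously on a threshold of 105 umol m$^{-2}$ s$^{-1}$
*and* a tolerance interval extending to 26 days; the daylight-mean
definition admits both.

The conversion constant $c_{PAR}$ (`par_conversion`, umol photons per Joule
of top-of-atmosphere shortwave) is a single effective factor folding the PAR
fraction of shortwave (~0.43), the energy-to-photon conversion of PAR (~4.6
umol J$^{-1}$) and bulk atmospheric and sea-surface losses. Its default,
0.4075 umol J$^{-1}$, is a calibration: it is the midpoint of the narrow
interval (about 0.407-0.408) for which fitting $E_{lim}$ and the tolerance
against a 50-degree reef cutoff returns a threshold of 105 umol m$^{-2}$
s$^{-1}$ — comfortably inside the 35-300 umol m$^{-2}$ s$^{-1}$ range of
published reef-limiting light estimates — with tolerances of 1-26 days. The factor is exposed in
`orbit_config()`, the fit report echoes it, and the fitted threshold scales
essentially linearly with it (about +13 umol m$^{-2}$ s$^{-1}$ per +10% in
the factor), so any other calibration can be substituted and its effect
inspected directly.

## Temperature scenarios

Scenarios are zonal means by unsigned latitude: per-latitude coldest-month
and warmest-month SST curves on the 0-90 degree grid. The generator produces
smooth poleward-declining gradients
$T(\phi) = T_{pole} + (T_{eq} - T_{pole})\cos^p\phi$, applied separately to
the two curves; $p = 2$ emulates the shape of zonal-mean climatologies well.
Four presets are bundled, all synthetic emulations (no climate-model or
observational data ship with the package):

```{r}
for (nm in c("modern-like", "eocene-x3-like", "eocene-x6-like", "eocene-x9-like"))
  print(scenario_preset(nm))
```

The preset endpoints were solved analytically so that the diagnostic
latitudes land on documented values: the "eocene-x6-like" coldest-month
curve first drops below 16 degC at 54 degrees and the "eocene-x9-like" at 71
degrees, while their warmest-month curves exceed 36 degC equatorward of 35
and 53 degrees respectively, emulating hothouse simulations in which the
thermal niche detaches from the equator. `read_scenario()` accepts
user-supplied per-latitude CSV files (hemispheres folded by unsigned
latitude, linear interpolation to the grid, no extrapolation); NetCDF input
is not supported in this build.

## The dark-day fit

`fit_light_cutoff()` asks: on the 5-umol grid over 20-400, what is the
smallest $E_{lim}$ for which *some* tolerance in 1-365 days zeroes
calcification at every latitude poleward of a target cutoff while permitting
it at the cutoff and equatorward, under unlimiting temperature?

```{r}
fit <- fit_light_cutoff(model_config(), target_cutoff = 50)
fit
```

With the default configuration the answer is $E_{lim} = 105$ umol m$^{-2}$
s$^{-1}$ with feasible tolerances of 1 to 26 days: at that threshold no
latitude up to 50 degrees has a single dark day, while 51 degrees already
accumulates 27. The fitted pair is degenerate by construction — a higher
threshold combined with a longer tolerance excludes the same latitudes — so
the model provides hypothetical combinations, not a unique estimate.

```{r}
prof <- yearly_profile(model_config(), scenario_preset("eocene-x6-like"))
prof[prof$latitude %in% 48:56, ]
```

Under the x6-like gradient the dark-day rule, not the 16 degC isotherm (at
54 degrees), terminates the profile at 50 degrees; equatorward of 35 degrees
the warm limit gates instead.

## Numerical choices and degenerate inputs

* Grid: latitudes 0-90 at 1 degree (configurable step), 365 integer days, no
  leap days; the southern hemisphere follows by symmetry.
* Equality conventions: a dark day requires PAR *strictly* below $E_{lim}$
  (reaching the threshold suffices to avoid darkness); a dark-day count equal
  to the tolerance is tolerated; envelope bounds are inclusive.
* `tanh` saturates to exactly 1 in double precision for $E_z/E_k \gtrsim
  19$; the response is treated as bounded by 1 inclusive.
* Polar night days have zero day length and exactly zero surface PAR; the
  daylight-mean flux on the shoulder days bordering polar night approaches
  the noon irradiance, which makes the yearly dark-day count not strictly
  monotone in latitude poleward of about 65 degrees (by up to ~11 days for
  intermediate thresholds). Equatorward of the polar circle — the band that
  determines reef cutoffs — counts are monotone.
* Sweeps iterate the Cartesian product of the $E_k$, $k_{par}z$, $E_{lim}$
  and tolerance axes in lexicographic order and are fully deterministic, as
  is every other computation in the package (the CLI seed option is reserved).
* Infeasible fits (e.g. a target cutoff poleward of the polar night margin
  with a capped tolerance range) return an empty result object, not an error.

## What the synthetic scenarios do and do not test

The generator emulates the *shape* of meridional SST gradients — smooth,
monotone poleward decline with prescribed endpoints — which is all the
temperature gate consumes. It does not emulate zonal asymmetry, coastal
upwelling, land-sea contrast, interannual variability, or polar
amplification structure beyond what the endpoints encode; passing tests
therefore demonstrate the limitation logic and its interplay, not fidelity
to any particular climate-model field. Likewise the solar engine is
top-of-atmosphere geometry with a constant effective transmission: clouds,
aerosol, seasonal turbidity and sea-ice are all folded into the calibrated
conversion factor, and species-specific photoacclimation, variable $E_k$
with depth, heterotrophy and aragonite saturation are deliberately outside
the model.

## Problem sizes used by the test-suite

The suite exercises the full 91-latitude x 365-day grid throughout (a
profile costs a few milliseconds); the brute-force solar oracle integrates
instantaneous irradiance at 1-minute resolution for 20 random latitude/day
pairs; the straight-loop model oracle re-computes yearly sums at 5 random
latitudes for 5 random configurations; the fit search spans the full 77-point
threshold grid with tolerances 1-365.
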