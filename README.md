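# coralight

A latitude-resolved box model of shallow-water coral calcification, for
ecologists and paleoclimatologists asking what caps the poleward edge of the
reef belt: temperature, or light.

Under modern climate the coldest-month 16 °C isotherm terminates reefs near
30–35° latitude. Under hothouse climates, water warmer than 16 °C reached far
poleward of 50°, yet fossil reefs are absent beyond ~50° paleolatitude. The
model separates the two controls by computing, for each degree of latitude, a
yearly calcification potential

```
G = Gmax · tanh(Ez / Ek) · f_darkdays · f_temp
```

where

* `Ez = Esurface · exp(-kpar · z)` is surface PAR attenuated to habitat depth
  (Lambert–Beer; photic depth `4.6 / kpar`),
* `tanh(Ez / Ek)` is the photosynthesis–irradiance saturation response with
  saturating intensity `Ek`,
* `f_darkdays` zeroes a latitude when its yearly count of "dark days" (surface
  PAR strictly below a threshold `Elim`) exceeds an integer darkness
  tolerance, and
* `f_temp` confines calcification to the 16–36 °C envelope of coldest-month /
  warmest-month mean SST.

Daily surface PAR is computed from orbital geometry (declination, sunset hour
angle, Sun–Earth distance; modern orbit by default), so no forcing data are
required; synthetic meridional SST gradients `T(φ) = Tpole + (Teq −
Tpole)·cos^p(φ)` stand in for climate-model or climatological fields. See the
vignette (`vignettes/coral-light-model.Rmd`) for the full model description,
parameter meanings, and design rationale.

## Worked example

Fit the dark-day threshold and tolerance that confine reefs to ≤ 50°
latitude under unlimiting temperature, then profile a hothouse-like scenario:

```r
library(coralight)

fit <- fit_light_cutoff(model_config(), target_cutoff = 50)
fit
#> <coral_fit>
#>   target poleward cutoff : 50 deg
#>   E_lim grid             : 20-400 umol m-2 s-1 (77 values)
#>   tolerance range        : 1-365 days
#>   PAR conversion factor  : 0.4075 umol J-1
#>   minimal E_lim          : 105 umol m-2 s-1
#>   feasible tolerances    : 1-26 days
```

The smallest dark-day threshold on the 5 µmol grid that can exclude all
latitudes beyond 50° while permitting 50° and equatorward is
`Elim = 105 µmol m⁻² s⁻¹`: at that threshold no latitude up to 50° has a
single dark day, while 51° already accumulates 27, so any tolerance from 1 to
26 days draws the cutoff at exactly 50°.

```r
prof <- yearly_profile(model_config(), scenario_preset("eocene-x6-like"))
prof[prof$latitude %in% c(0, 34, 35, 45, 50, 51, 54, 60), ]
#>    latitude yearly_G yearly_pct dark_days limiting_factor
#> 0         0      0.0       0.00         0            heat
#> 34       34      0.0       0.00         0            heat
#> 35       35    359.1     100.00         0            none
#> 45       45    350.1      97.50         0           light
#> 50       50    340.6      94.85         0           light
#> 51       51      0.0       0.00        27       dark_days
#> 54       54      0.0       0.00        64        multiple
#> 60       60      0.0       0.00       107        multiple
poleward_cutoff(prof)
#> [1] 50
```

Under this x6-CO₂-like gradient the coldest month stays above 16 °C out to
54°, yet the profile ends at 50°: the dark-day rule, not temperature, caps
the poleward edge (`limiting_factor` is `"dark_days"` at 51–53°, and
`"multiple"` once the cold gate also closes at 54°). Equatorward of 35° the
warmest month exceeds 36 °C and the heat gate closes instead. `yearly_pct`
is the yearly calcification as a percentage of the scenario maximum.

A command-line front end wrapping the same functions lives at
`inst/cli/coralight.R` (subcommands `profile`, `sweep`, `fit`, `synth`).

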