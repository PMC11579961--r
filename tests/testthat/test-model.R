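unlimiting <- constant_scenario(26)

test_that("daily calcification vanishes under polar night and closed gates", {
  cfg <- model_config(light = light_params(tolerance_days = NULL))
  dec_solstice <- orbital_event_days(cfg$orbit)["december_solstice"]
  expect_equal(daily_calcification(85, dec_solstice, cfg, unlimiting),
               0, ignore_attr = TRUE)
  # coldest month below 16 degC zeroes every day of the year at that latitude
  modern <- scenario_preset("modern-like")
  lat_cold <- crossing_latitude(modern, 16)
  g <- daily_calcification(lat_cold, c(1, 80, 172, 266, 355), cfg, modern)
  expect_equal(g, rep(0, 5))
})

test_that("daily calcification reaches G_max * tanh(1) when E_z = E_k", {
  es <- surface_par_series(30)[100]
  lp <- light_params(E_k = es * exp(-0.75), tolerance_days = NULL)
  cfg <- model_config(G_max = 2.5, light = lp)
  expect_equal(daily_calcification(30, 100, cfg, unlimiting),
               2.5 * tanh(1))
})

test_that("daily calcification factorizes into the three limitation terms", {
  set.seed(3)
  cfg <- model_config()
  for (i in 1:10) {
    lat <- sample(0:90, 1); d <- sample(1:365, 1)
    es <- surface_par_series(lat, cfg$orbit)
    expected <- cfg$G_max *
      f_light(attenuate(es[d], cfg$light$k_par, cfg$light$z), cfg$light$E_k) *
      f_darkdays(count_dark_days(es, cfg$light$E_lim),
                 cfg$light$tolerance_days) *
      f_temp(unlimiting$coldest_month_sst[lat + 1],
             unlimiting$warmest_month_sst[lat + 1], cfg$envelope)
    expect_identical(daily_calcification(lat, d, cfg, unlimiting), expected)
  }
})

test_that("unlimiting-temperature profile peaks at the equator and declines poleward", {
  cfg <- model_config(light = light_params(E_k = 50, k_par = 0.05, z = 15,
                                           tolerance_days = NULL))
  prof <- yearly_profile(cfg, unlimiting)
  expect_equal(max(prof$yearly_pct), 100)
  expect_gt(prof$yearly_pct[prof$latitude == 0], 99.9)
  # non-increasing poleward (tiny equator-side wiggle from orbital eccentricity)
  expect_true(all(diff(prof$yearly_pct) <= 0.01))
  expect_true(all(prof$yearly_G >= 0 & prof$yearly_G <= 365 * cfg$G_max))
})

test_that("the default dark-day rule cuts the unlimiting profile at 50 degrees", {
  cfg <- model_config()  # E_lim 105, tolerance 26
  prof <- yearly_profile(cfg, unlimiting)
  expect_gt(prof$yearly_G[prof$latitude == 50], 0)
  expect_true(all(prof$yearly_G[prof$latitude > 50] == 0))
  expect_equal(poleward_cutoff(prof), 50)
  expect_true(all(prof$limiting_factor[prof$latitude > 50] == "dark_days"))
})

test_that("a scenario entirely below the envelope yields zero everywhere", {
  frozen <- constant_scenario(5)
  prof <- yearly_profile(model_config(), frozen)
  expect_true(all(prof$yearly_G == 0))
  expect_true(all(prof$yearly_pct == 0))
  expect_true(all(prof$limiting_factor %in% c("cold", "multiple")))
  expect_true(is.na(poleward_cutoff(prof)))
})

test_that("profile latitudes outside the scenario grid are refused", {
  narrow <- temperature_scenario(0:45, rep(26, 46), rep(27, 46))
  expect_error(yearly_profile(model_config(), narrow), "scenario grid")
  expect_error(daily_calcification(50, 1, model_config(), narrow),
               "scenario grid")
})

test_that("a degenerate single-point sweep reproduces yearly_profile exactly", {
  cfg <- model_config()
  sw <- calc_sweep(cfg, unlimiting)
  expect_equal(nrow(sw), 1)
  prof <- attr(sw, "profiles")[[1]]
  expect_identical(as.data.frame(prof),
                   as.data.frame(yearly_profile(cfg, unlimiting)))
  expect_equal(sw$cutoff, poleward_cutoff(prof))
  expect_error(calc_sweep(cfg, unlimiting, E_k = numeric(0)), "E_k")
})

test_that("calcification never increases with optical thickness or E_k", {
  cfg <- model_config(light = light_params(tolerance_days = NULL))
  sw_kz <- calc_sweep(cfg, unlimiting, kpar_z = c(0.15, 0.75, 1.5, 3.0))
  profs <- attr(sw_kz, "profiles")
  for (i in seq_len(length(profs) - 1))
    expect_true(all(profs[[i + 1]]$yearly_G <= profs[[i]]$yearly_G + 1e-12))
  sw_ek <- calc_sweep(cfg, unlimiting, E_k = c(50, 100, 150, 200, 300))
  profs <- attr(sw_ek, "profiles")
  for (i in seq_len(length(profs) - 1))
    expect_true(all(profs[[i + 1]]$yearly_G <= profs[[i]]$yearly_G + 1e-12))
})

test_that("sweep rows come in lexicographic order over the axes", {
  sw <- calc_sweep(model_config(), unlimiting, E_k = c(100, 50),
                   kpar_z = c(1.5, 0.75), keep_profiles = FALSE)
  expect_equal(sw$E_k, c(50, 50, 100, 100))
  expect_equal(sw$kpar_z, c(0.75, 1.5, 0.75, 1.5))
})

test_that("the poleward cutoff is monotone in E_lim and tolerance", {
  cfg <- model_config()
  elims <- c(50, 105, 200, 300)
  tols <- c(1, 26, 100)
  sw <- calc_sweep(cfg, unlimiting, E_lim = elims, tolerance_days = tols,
                   keep_profiles = FALSE)
  cut <- function(el, tl) sw$cutoff[sw$E_lim == el & sw$tolerance_days == tl]
  for (tl in tols) {
    cuts <- vapply(elims, cut, numeric(1), tl = tl)
    expect_true(all(diff(cuts) <= 0))   # higher threshold never extends range
  }
  for (el in elims) {
    cuts <- vapply(tols, cut, numeric(1), el = el)
    expect_true(all(diff(cuts) >= 0))   # more tolerance never shrinks range
  }
})

test_that("vectorized yearly totals match a straight-loop re-implementation", {
  set.seed(21)
  for (i in 1:5) {
    lp <- light_params(E_k = runif(1, 50, 300),
                       E_lim = runif(1, 20, 400),
                       k_par = runif(1, 0.15, 3) / 15, z = 15,
                       tolerance_days = sample(1:365, 1))
    cfg <- model_config(G_max = runif(1, 0.5, 3), light = lp)
    sc <- scenario_preset(sample(c("modern-like", "eocene-x3-like",
                                   "eocene-x6-like", "eocene-x9-like"), 1))
    prof <- yearly_profile(cfg, sc)
    for (lat in sample(0:90, 5)) {
      expect_equal(prof$yearly_G[prof$latitude == lat],
                   loop_yearly_G(lat, cfg, sc), tolerance = 1e-9)
    }
  }
})

test_that("with the dark-day rule disabled the cutoff is set by the 16 degC crossing", {
  cfg <- model_config(light = light_params(tolerance_days = NULL))
  set.seed(5)
  for (i in 1:5) {
    Tp <- runif(1, 0, 12); Te <- Tp + runif(1, 10, 25)
    sp <- synth_gradient_spec(Te, Tp, min(Te + 4, 35.5), Tp + 4,
                              shape_exponent = runif(1, 1, 3))
    sc <- synth_scenario(sp)
    cross <- crossing_latitude(sc, 16)
    if (is.na(cross) || cross == 0) next
    expect_equal(poleward_cutoff(yearly_profile(cfg, sc)), cross - 1)
  }
})

test_that("fitting the dark-day threshold recovers the headline configuration", {
  fit <- fit_light_cutoff(model_config(), target_cutoff = 50)
  expect_true(fit$feasible)
  expect_equal(fit$E_lim, 105)
  expect_equal(fit$tolerance, c(1L, 26L))
  # brute-force confirmation of the feasible tolerance interval at that E_lim
  dd <- rowSums(surface_par_grid(0:90) < fit$E_lim)
  feasible_tols <- Filter(function(tol)
    all(dd[0:90 > 50] > tol) && all(dd[0:90 <= 50] <= tol), 1:365)
  expect_equal(range(feasible_tols), as.numeric(fit$tolerance))
  # equatorward counts are all zero, so the interval starts at 1 and ends one
  # below the first poleward count
  expect_true(all(dd[0:90 <= 50] == 0))
  expect_equal(fit$tolerance[2], as.integer(dd[52] - 1))  # row 52 is 51 deg
})

test_that("an unreachable target produces an empty fit result, not an error", {
  fit <- fit_light_cutoff(model_config(), target_cutoff = 89,
                          tolerance_range = 1:100)
  expect_false(fit$feasible)
  expect_true(is.na(fit$E_lim))
  expect_output(print(fit), "no feasible combination")
})
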