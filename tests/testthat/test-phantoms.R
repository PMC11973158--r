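test_that("phantom generation is deterministic in config + seed", {
  cfg <- phantom_config(grid_size = 32, noise_sd = 0.02, seed = 11)
  expect_identical(unclass(make_complex_phantom(cfg)),
                   unclass(make_complex_phantom(cfg)))
  other <- make_complex_phantom(phantom_config(grid_size = 32, noise_sd = 0.02,
                                               seed = 12))
  expect_true(any(Mod(make_complex_phantom(cfg) - other) > 0))
})

test_that("noiseless phantoms have bounded magnitude and principal-value phase", {
  ph <- make_complex_phantom(phantom_config(grid_size = 48, seed = 3))
  expect_true(all(Mod(ph) >= 0 & Mod(ph) <= 1 + 1e-12))
  expect_true(all(Arg(ph) > -pi & Arg(ph) <= pi))
})

test_that("phantom configuration is validated", {
  expect_error(phantom_config(grid_size = 8), "grid_size")
  expect_error(phantom_config(noise_sd = -0.1), "noise_sd")
})

test_that("heating scenario validation enforces the reference frame", {
  expect_error(heating_scenario(c(16, 16), 4, n_timepoints = 1), "n_timepoints")
  expect_error(heating_scenario(c(16, 16), 4, n_timepoints = 18), "n_timepoints")
  expect_error(heating_scenario(c(16, 16), 4, n_timepoints = 3,
                                delta_T_peak_per_tp = c(1, 2, 3)), "reference")
  expect_error(heating_scenario(c(16, 16), -1, n_timepoints = 3), "hotspot_sigma")
})

test_that("zero heating leaves every frame identical to the reference", {
  ph <- make_complex_phantom(phantom_config(grid_size = 32, seed = 5))
  scen <- heating_scenario(c(16, 16), 4, n_timepoints = 4,
                           delta_T_peak_per_tp = c(0, 0, 0, 0))
  series <- simulate_heating_series(ph, scen, default_constants())
  for (t in 2:4) {
    expect_identical(unclass(series$frames[[t]]), unclass(series$frames[[1]]))
  }
})

test_that("heating injects exactly the PRF phase and preserves magnitude", {
  constants <- thermo_constants(B0 = 1.5, TE = 19.1e-3)
  # hand evaluation of the phase-per-degree slope gamma*alpha*B0*TE
  slope_hand <- (2 * pi * 42.577e6) * (-0.01e-6) * 1.5 * 0.0191
  expect_equal(prf_phase_per_degC(constants), slope_hand, tolerance = 1e-12)

  fx <- tiny_heated_pair(grid = 32, delta_T_peak = 3, constants = constants)
  f0 <- fx$series$frames[[1]]; f1 <- fx$series$frames[[2]]
  expect_equal(Mod(unclass(f1)), Mod(unclass(f0)), tolerance = 1e-12)
  dT_true <- scenario_delta_T(fx$scenario, 32, 2)
  dphi <- Arg(unclass(f1) * Conj(unclass(f0)))
  ok <- Mod(unclass(f0)) > 0         # phase undefined on zero-magnitude voxels
  expect_lt(max(abs(dphi - slope_hand * dT_true)[ok]), 1e-10)
})

test_that("noiseless thermometry round trip recovers the injected temperature rise", {
  constants <- default_constants()
  ph <- make_complex_phantom(phantom_config(grid_size = 48, seed = 21))
  scen <- heating_scenario(c(24, 26), 5, n_timepoints = 5, peak_delta_T = 6)
  series <- simulate_heating_series(ph, scen, constants)
  tmaps <- temperature_series(series)
  ok <- Mod(unclass(ph)) > 0
  for (t in 1:5) {
    dT_true <- scenario_delta_T(scen, 48, t)
    expect_lt(max(abs(tmaps[[t]] - dT_true)[ok]), 1e-6)
  }
})

test_that("complex noise leaves the recovered temperature unbiased", {
  constants <- default_constants()
  fx <- tiny_heated_pair(grid = 32, delta_T_peak = 3, seed = 31,
                         constants = constants)
  f0 <- unclass(fx$series$frames[[1]]); f1 <- unclass(fx$series$frames[[2]])
  peak_v <- fx$scenario$hotspot_center
  dT_true <- scenario_delta_T(fx$scenario, 32, 2)[peak_v[1], peak_v[2]]
  s <- 0.01 * max(Mod(f0))
  set.seed(99)
  errs <- replicate(150, {
    n0 <- add_complex_noise(f0, s); n1 <- add_complex_noise(f1, s)
    tm <- temperature_map(phase_difference(n0, n1), constants)
    tm[peak_v[1], peak_v[2]] - dT_true
  })
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * se)
})

test_that("the generator does not pre-unwrap large heating phase shifts", {
  constants <- default_constants()
  slope <- prf_phase_per_degC(constants)
  dT_wrap <- 1.2 * pi / abs(slope)      # injected |dphi| > pi at the peak
  ph <- make_complex_phantom(phantom_config(grid_size = 32, seed = 41))
  scen <- heating_scenario(c(16, 16), 4, n_timepoints = 2,
                           delta_T_peak_per_tp = c(0, dT_wrap))
  series <- simulate_heating_series(ph, scen, constants)
  dphi <- phase_difference(series$frames[[1]], series$frames[[2]])
  # recovered phase is the principal value, not the injected ramp
  injected <- slope * dT_wrap
  wrapped <- Arg(exp(1i * injected))
  expect_equal(dphi[16, 16], wrapped, tolerance = 1e-9)
  expect_gt(abs(injected - wrapped), 1)   # genuinely wrapped case
})
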