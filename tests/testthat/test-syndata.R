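test_that("dose response follows the Hill closed forms", {
  pk <- peak_spec(730, 16, 60, +1, hill_K = 1e-9, hill_h = 0.7,
                  max_fold_change = 1.5)
  expect_equal(dose_response(0, pk), 60)
  expect_equal(dose_response(1e3, pk), 60 * 2.5, tolerance = 1e-6) # saturation
  expect_equal(dose_response(1e-9, pk), 60 * (1 + 1.5 / 2))        # c = K
  down <- peak_spec(785, 14, 40, -1, hill_K = 1e-9, hill_h = 0.7,
                    max_fold_change = 0.8)
  expect_equal(dose_response(1e-9, down), 40 * (1 - 0.8 / 2))
  cs <- 10^seq(-15, -3, by = 0.5)
  expect_true(all(diff(dose_response(cs, pk)) > 0))
  expect_true(all(diff(dose_response(cs, down)) < 0))
  expect_error(dose_response(-1e-9, pk), "nonnegative")
})

test_that("a null configuration produces an all-zero spectrum", {
  cfg <- generator_config(
    peak_library = list(), si_line = peak_spec(520, 12, 0),
    baseline = list(offset = 0, slope = 0, g_amp = 0, g_center = 1400,
                    g_width = 300),
    noise_sd = 0, wavenumbers = seq(300, 1800, 10))
  s <- simulate_spectrum(cfg, 0)
  expect_equal(s$intensity[[1]], rep(0, length(wavenumbers(s))))
})

test_that("the noise-free spectrum peaks at the strongest band", {
  cfg <- generator_config(noise_sd = 0, si_line = peak_spec(520, 12, 0),
                          baseline = list(offset = 0, slope = 0, g_amp = 0,
                                          g_center = 1400, g_width = 300))
  s <- simulate_spectrum(cfg, 0)
  amps <- vapply(cfg$peak_library, function(pk) dose_response(0, pk), 1)
  strongest <- cfg$peak_library[[which.max(amps)]]$center
  got <- wavenumbers(s)[which.max(s$intensity[[1]])]
  expect_lt(abs(got - strongest), 3)
})

test_that("identical seeds give bit-identical spectra and datasets", {
  cfg <- tiny_cfg(seed = 9)
  expect_identical(simulate_spectrum(cfg, 1e-9, seed = 4),
                   simulate_spectrum(cfg, 1e-9, seed = 4))
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("class counts follow the closed form for arbitrary layouts", {
  for (s in 1:3) {
    cfg <- generator_config(metal = "Cr6",
                            concentrations = decade_ladder("Cr6")[1:(s + 1)],
                            map_shape = c(s, 2L), n_maps_per_class = 2L,
                            n_control_surfaces = s,
                            wavenumbers = seq(300, 1800, 100), seed = s)
    ds <- simulate_dataset(cfg)
    expect_equal(dataset_summary(ds)$n, expected_class_counts(cfg)$n)
  }
  one <- generator_config(map_shape = c(1L, 1L), n_maps_per_class = 1L,
                          n_control_surfaces = 1L,
                          wavenumbers = seq(300, 1800, 100))
  expect_true(all(dataset_summary(simulate_dataset(one))$n == 1L))
})

test_that("without noise and gains, concentration only moves bands in their direction", {
  cfg <- generator_config(noise_sd = 0, surface_gain_sd = 0,
                          replicate_gain_sd = 0)
  lad <- cfg$concentrations
  s_lo <- simulate_spectrum(cfg, lad[2])$intensity[[1]]
  s_hi <- simulate_spectrum(cfg, lad[6])$intensity[[1]]
  wn <- cfg$wavenumbers
  for (pk in cfg$peak_library) {
    at <- which.min(abs(wn - pk$center))
    expect_equal(sign(s_hi[at] - s_lo[at]), pk$response_direction)
  }
  # the difference trace is exactly the sum of Lorentzian amplitude shifts:
  # baseline, silicon line and gains cancel
  want <- rep(0, length(wn))
  for (pk in cfg$peak_library) {
    dA <- dose_response(lad[6], pk) - dose_response(lad[2], pk)
    want <- want + dA * (pk$width / 2)^2 / ((wn - pk$center)^2 + (pk$width / 2)^2)
  }
  expect_equal(s_hi - s_lo, want, tolerance = 1e-9)
})

test_that("matrix shift adds background but leaves the internal standard alone", {
  di <- generator_config(noise_sd = 0, wavenumbers = seq(300, 1800, 5))
  expect_identical(make_matrix_shifted(di, "DI"), di)
  tap <- make_matrix_shifted(di, "tap")
  s_di <- simulate_spectrum(di, 0)$intensity[[1]]
  s_tap <- simulate_spectrum(tap, 0)$intensity[[1]]
  expect_gt(max(abs(s_tap - s_di)), 1)          # background really changed
  expect_identical(tap$si_line, di$si_line)     # Si line spec untouched
  expect_identical(tap$peak_library, di$peak_library)
  expect_equal(tap$water_matrix, "tap")
  expect_error(make_matrix_shifted(di, "seawater"))
})
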