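test_that("first-order fits recover exact and noisy rate constants", {
  times <- seq(0, 7200, by = 600)
  exact <- tibble::tibble(time_s = times, conc_M = 2e-5 * exp(-1e-4 * times))
  expect_equal(fit_first_order(exact)$k_obs, 1e-4, tolerance = 1e-12)

  const <- tibble::tibble(time_s = times, conc_M = rep(2e-5, length(times)))
  expect_equal(fit_first_order(const)$k_obs, 0)

  ks <- vapply(1:50, function(s) {
    tr <- gen_kinetics(0.022, ra = 2e-6, noise_cv = 0.02, seed = s)
    fit_first_order(tr)$k_obs
  }, numeric(1))
  k_true <- 1e8 * 0.022 * 2e-6 / 2.76e5
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.03)

  bad <- tibble::tibble(time_s = times,
                        conc_M = c(-1, rep(1e-5, length(times) - 1)))
  expect_error(fit_first_order(bad), class = "lakephoto_invalid_argument")
})

test_that("actinometry scale round-trips and is linear in lamp intensity", {
  tr1 <- gen_kinetics(species = "PNA", lamp_scale = 1)
  expect_equal(actinometry_scale(tr1, 0.01), 1, tolerance = 1e-6)

  tr2 <- gen_kinetics(species = "PNA", lamp_scale = 2)
  expect_equal(actinometry_scale(tr2, 0.01), 2, tolerance = 1e-6)

  # quantum yield from the configured coefficients
  const <- photo_constants()
  expect_equal(const$phi_pna_slope * 0.01 + const$phi_pna_intercept,
               0.00319, tolerance = 1e-12)
})

test_that("rate of light absorption behaves as a one-term sum on a toy", {
  grid <- 290:550
  z <- rep(0, length(grid))
  z[grid == 400] <- 3e-9
  fl <- light_field(tibble::tibble(wavelength_nm = grid, z_daily = z))
  spec <- absorbance_spectrum(c(250, 600), c(5, 5)) # flat 5 m^-1
  ra <- rate_light_absorption(spec, fl, pathlength_cm = 1.1)
  frac <- 1 - exp(-0.05 * 1.1)
  expect_equal(ra, 3e-9 * frac / 1.1 * 1000, tolerance = 1e-12)

  # zero absorbance, linearity in irradiance
  none <- absorbance_spectrum(c(250, 600), c(0, 0))
  expect_equal(rate_light_absorption(none, fl), 0)
  expect_equal(rate_light_absorption(spec, fl, scale = 2), 2 * ra)
})

test_that("quantum-yield round-trip recovers the planted value", {
  fl <- light_field()
  spec <- gen_spectrum(2, 0.018)
  ra <- rate_light_absorption(spec, fl)
  tr <- gen_kinetics(0.022, ra = ra, noise_cv = 0)
  qy <- apparent_quantum_yield(fit_first_order(tr)$k_obs, ra)
  expect_equal(qy$phi_app, 0.022, tolerance = 1e-9)

  expect_equal(apparent_quantum_yield(1e-5, ra = 1)$one_o2_ss_exp, 1e-13)
  r <- apparent_quantum_yield(fit_first_order(tr)$k_obs, ra,
                              phi_srnom = 0.0214)
  expect_equal(r$phi_ratio_srnom, 0.022 / 0.0214, tolerance = 1e-9)
  expect_warning(apparent_quantum_yield(1, ra = 1e-10),
                 class = "lakephoto_suspect_result")
})

test_that("quantum yield is recovered within 5% at 2% noise in >= 95% of seeds", {
  fl <- light_field()
  spec <- gen_spectrum(2, 0.018)
  ra <- rate_light_absorption(spec, fl)
  hits <- vapply(1:50, function(s) {
    tr <- gen_kinetics(0.022, ra = ra, noise_cv = 0.02, seed = s)
    phi <- apparent_quantum_yield(fit_first_order(tr)$k_obs, ra)$phi_app
    abs(phi - 0.022) / 0.022 < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("euphotic depth follows the DOC power law", {
  expect_equal(euphotic_depth(1), 4.6 / 0.15 * 100, tolerance = 1e-12)
  expect_equal(euphotic_depth(4), 4.6 / (0.15 * 4^1.08) * 100,
               tolerance = 1e-12)
  expect_equal(euphotic_depth(8) / euphotic_depth(4), 2^-1.08,
               tolerance = 1e-12)
  expect_error(euphotic_depth(0), class = "lakephoto_invalid_argument")
})

test_that("diffuse attenuation follows the printed formula and separability", {
  expect_equal(kd_lambda(4, 440, formula_units = "cm"),
               exp(-0.01347 * 440 + 5.36 * 4^0.157), tolerance = 1e-12)
  # default reads the formula in m^-1, converting to cm^-1
  expect_equal(kd_lambda(4, 440), kd_lambda(4, 440, "cm") / 100)
  for (doc in c(2, 4, 10)) {
    kd <- kd_lambda(doc, 290:550)
    expect_true(all(diff(kd) < 0))
    expect_equal(kd_lambda(doc, 290) / kd_lambda(doc, 550),
                 exp(0.01347 * 260), tolerance = 1e-12)
  }
  expect_error(kd_lambda(4, 200), class = "lakephoto_invalid_argument")
})

test_that("steady-state model matches a one-wavelength hand calculation", {
  grid <- 290:550
  z <- rep(0, length(grid))
  z[grid == 400] <- 2.5e-9
  fl <- light_field(tibble::tibble(wavelength_nm = grid, z_daily = z),
                    cf = 0.6, f_backscatter = 0.02, f_abs_cdom = 0.9,
                    surface_reflection = 0.066, pathlength_factor = 1.2)
  lake <- lake_optical_model(4)
  ss <- steady_state_1o2(0.022, fl, lake)

  kd <- exp(-0.01347 * 400 + 5.36 * 4^0.157) / 100 # cm^-1
  zeu <- 4.6 / (0.15 * 4^1.08) * 100               # cm
  z_eff <- 2.5e-9 * (1 - 0.066) * 1.2
  expected_euph <- 0.022 / 2.76e5 * 0.6 *
    z_eff * (1 - exp(-kd * zeu)) / zeu * (1 - 0.02) * 0.9 * 1000
  expected_ns <- 0.022 / 2.76e5 * 0.6 * z_eff * kd * (1 - 0.02) * 0.9 * 1000
  expect_equal(ss$c_euphotic, expected_euph, tolerance = 1e-12)
  expect_equal(ss$c_near_surface, expected_ns, tolerance = 1e-12)
})

test_that("steady state obeys limits, bounds and homogeneity", {
  fl <- light_field()
  lake <- lake_optical_model(4)
  expect_equal(steady_state_1o2(0, fl, lake)$c_euphotic, 0)

  ss <- steady_state_1o2(0.022, fl, lake)
  expect_lte(ss$c_euphotic, ss$c_near_surface)

  # attenuation -> 0: euphotic average approaches the near-surface value
  tiny <- lake
  tiny$z_euphotic_cm <- 1e-6
  st <- steady_state_1o2(0.022, fl, tiny)
  expect_equal(st$c_euphotic / st$c_near_surface, 1, tolerance = 1e-6)

  # linear in phi, CF and irradiance amplitude
  expect_equal(steady_state_1o2(0.044, fl, lake)$c_euphotic,
               2 * ss$c_euphotic, tolerance = 1e-12)
  fl2 <- light_field(cf = 0.3)
  expect_equal(steady_state_1o2(0.022, fl2, lake)$c_euphotic,
               ss$c_euphotic / 2, tolerance = 1e-12)
  fl3 <- light_field(gen_solar_spectrum(z_max = 4e-9))
  expect_equal(steady_state_1o2(0.022, fl3, lake)$c_euphotic,
               2 * ss$c_euphotic, tolerance = 1e-12)

  # epilimnion variant only with a depth, and between the two extremes
  expect_true(is.na(ss$c_epilimnion))
  ep <- steady_state_1o2(0.022, fl, lake, epilimnion_depth_cm = 300)
  expect_gt(ep$c_epilimnion, ep$c_euphotic)
  expect_lt(ep$c_epilimnion, ep$c_near_surface)
})

test_that("euphotic concentration rises monotonically with DOC", {
  fl <- light_field()
  doc <- seq(1, 15, by = 0.5)
  cc <- vapply(doc, function(d) {
    steady_state_1o2(0.022, fl, lake_optical_model(d))$c_euphotic
  }, numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("half-life arithmetic and unit conversion are correct", {
  expect_equal(half_life(log(2), 1, seconds_per_month = 1), 1)
  expect_equal(half_life(1.8e6, 2 * 3.6e-16),
               half_life(1.8e6, 3.6e-16) / 2)
  expect_error(half_life(0, 1), class = "lakephoto_invalid_argument")
})

test_that("screening classes match brute-force enumeration", {
  tau <- 0.8
  c_ss <- 4e-15
  # boundary: t_half == tau exactly
  k_eq <- log(2) / (c_ss * tau * 12 * 86400 * 30.44)
  res <- screen_compounds(tibble::tibble(name = "x", k_rxn = k_eq),
                          c_ss, tau)
  expect_equal(res$log10_ratio, 0, tolerance = 1e-12)
  expect_equal(res$fate_class, "comparable")

  res100 <- screen_compounds(tibble::tibble(name = "y", k_rxn = k_eq / 100),
                             c_ss, tau)
  expect_equal(res100$log10_ratio, 2, tolerance = 1e-12)
  expect_equal(res100$fate_class, "slower")

  cmp <- gen_compounds(106, seed = 3)
  out <- screen_compounds(cmp, c_ss, tau)
  expect_equal(out$fate_class, screen_brute(cmp$k_rxn, c_ss, tau))
  expect_equal(table(out$fate_class), table(screen_brute(cmp$k_rxn, c_ss, tau)))

  empty <- screen_compounds(tibble::tibble(name = character(),
                                           k_rxn = numeric()), c_ss, tau)
  expect_equal(nrow(empty), 0)
})
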