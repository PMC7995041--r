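test_that("occlusion law is exact when open, finite when closed, monotone between", {
  expect_identical(occlusion_to_resistance(0, R_open = 10, R_span = 10,
                                           delta = 0.01), 10)
  expect_equal(occlusion_to_resistance(0.5, R_open = 10, R_span = 10,
                                       delta = 0.01),
               10 + 10 * 0.5 / 0.51, tolerance = 1e-12)
  expect_true(is.finite(occlusion_to_resistance(1, 10, 10, 0.01)))
  # strictly increasing in d for several taper constants
  for (delta in c(0.01, 0.25, 0.75)) {
    r <- occlusion_to_resistance(seq(0, 1, by = 0.05), 10, 10, delta)
    expect_true(all(diff(r) > 0))
  }
  expect_error(occlusion_to_resistance(-0.1, 10, 10), "\\[0, 1\\]")
  expect_error(occlusion_to_resistance(1.1, 10, 10), "\\[0, 1\\]")
})

test_that("threshold maps give the calibrated 20/8 cmH2O at midpoints with the documented screw directions", {
  cfg <- diverter_config()
  thr <- switching_thresholds(screw_settings(), cfg)
  expect_equal(unname(thr), c(20, 8))
  # closing SC raises PIP, closing FC lowers it
  base <- switching_thresholds(screw_settings(d_SC = 0.5, d_FC = 0.5), cfg)
  up_sc <- switching_thresholds(screw_settings(d_SC = 0.8, d_FC = 0.5), cfg)
  up_fc <- switching_thresholds(screw_settings(d_SC = 0.5, d_FC = 0.8), cfg)
  expect_gt(up_sc[["P_high"]], base[["P_high"]])
  expect_lt(up_fc[["P_high"]], base[["P_high"]])
  # hysteresis band survives every admissible screw corner
  for (dsc in c(0, 1)) for (dfc in c(0, 1)) {
    thr <- switching_thresholds(screw_settings(d_SC = dsc, d_FC = dfc), cfg)
    expect_gt(thr[["P_high"]], thr[["P_low"]])
  }
  # a threshold map that can collapse the band is rejected at load
  expect_error(diverter_config(k_FC = 30), "no oscillation possible")
})

test_that("diverter flow laws: constant-flow charging, Ohm-analog discharge", {
  cfg <- diverter_config(eta_insp = 0.8, Q_src = 0.5)
  scr <- screw_settings()
  for (p in c(0, 10, 25)) {
    expect_equal(lung_flow("INSPIRATION", p, scr, cfg), 0.4)
  }
  expect_equal(lung_flow("EXPIRATION", 0, scr, cfg, R_exp = 100), 0)
  expect_equal(lung_flow("EXPIRATION", 20, scr, cfg, R_exp = 100), -0.2)
})

test_that("phase rule switches at the thresholds and holds inside the band", {
  expect_identical(next_phase("INSPIRATION", 20, 20, 8), "EXPIRATION")
  expect_identical(next_phase("INSPIRATION", 19.99, 20, 8), "INSPIRATION")
  expect_identical(next_phase("EXPIRATION", 10, 20, 8), "EXPIRATION")
  expect_identical(next_phase("EXPIRATION", 8, 20, 8), "INSPIRATION")
  # idempotent inside the hysteresis band
  for (p in seq(8.5, 19.5, by = 1)) {
    for (ph in c("INSPIRATION", "EXPIRATION")) {
      expect_identical(next_phase(ph, p, 20, 8), ph)
    }
  }
  expect_error(next_phase("INSPIRATION", 10, 8, 8), "exceed")
})

test_that("characteristic time equals chamber volume over volumetric flow", {
  geom <- geometry_parameters(D = 0.088, h = 0.0024)
  q <- 5e-4  # 30 L/min in m^3/s
  tc <- characteristic_time(geom, vol_flow = q)
  # independent computation: cylinder volume / flow
  expect_equal(tc, (pi * 0.088^2 / 4 * 0.0024) / q, tolerance = 1e-15)
  expect_equal(tc, 0.0292, tolerance = 2e-3)
  # mass-flow form agrees with the volumetric overload
  expect_equal(characteristic_time(geom, v = 0.8, mdot = q / 0.8), tc)
  # scaling laws: quadratic in D, inverse in mass flow, linear in h
  expect_equal(characteristic_time(geometry_parameters(D = 2 * 0.088,
                                                       h = 0.0024),
                                   vol_flow = q), 4 * tc)
  expect_equal(characteristic_time(geom, v = 0.8, mdot = q / 0.8 / 2), 2 * tc)
  expect_equal(characteristic_time(geometry_parameters(D = 0.088,
                                                       h = 0.0048),
                                   vol_flow = q), 2 * tc)
  expect_error(characteristic_time(geom, vol_flow = 0), "vol_flow")
  expect_error(characteristic_time(geom), "supply either")
  expect_error(geometry_parameters(D = -1), "D")
})
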