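test_that("noise-free fixtures are recovered exactly by both segmentation routes", {
  spec <- fixture_spec(PIP = 17, PEEP = 11, T_i = 1, T_e = 3,
                       n_cycles = 10, noise_sd = 0)
  rec <- make_synthetic_waveform(spec)
  expect_equal(max(rec$P_alv), 17)
  expect_equal(min(rec$P_alv), 11)

  # route 1: phase labels
  cyc <- segment_breaths(rec)
  expect_true(nrow(cyc) %in% c(9, 10))
  expect_equal(cyc$PIP, rep(17, nrow(cyc)))
  expect_equal(cyc$PEEP, rep(11, nrow(cyc)))
  expect_equal(cyc$period, rep(4, nrow(cyc)))
  expect_equal(cyc$T_i, rep(1, nrow(cyc)))

  # route 2: bare pressure trace
  bare <- data.frame(t = rec$t, P_alv = rec$P_alv)
  cyc2 <- segment_breaths(bare)
  expect_true(nrow(cyc2) %in% c(9, 10))
  expect_equal(unique(round(cyc2$PIP, 10)), 17)
  expect_equal(unique(round(cyc2$PEEP, 10)), 11)
  expect_equal(unique(round(cyc2$period, 6)), 4)
})

test_that("phase-label and trace segmentation agree on the simulated waveform", {
  rec <- simulate_ventilator(quick_config(duration = 30))
  cyc_ph <- segment_breaths(rec)
  cyc_tr <- segment_breaths(data.frame(t = rec$t, P_alv = rec$P_alv))
  expect_equal(nrow(cyc_ph), nrow(cyc_tr))
  expect_true(all(abs(cyc_ph$PIP - cyc_tr$PIP) < 0.1))
  expect_true(all(abs(cyc_ph$PEEP - cyc_tr$PEEP) < 0.1))
})

test_that("metrics summarise constant and hand-computed cycle sets", {
  mk <- function(periods, T_i = 1, T_e = periods - T_i, PIP = 17,
                 PEEP = 11) {
    n <- length(periods)
    starts <- cumsum(c(0, periods[-n]))
    structure(data.frame(
      t_insp_start = starts, t_exp_start = starts + T_i,
      t_end = starts + periods, PIP = PIP, PEEP = PEEP, T_i = T_i,
      T_e = T_e, period = periods, tidal_volume = 0.3,
      triggered = FALSE), class = c("breath_cycles", "data.frame"))
  }
  # 15 identical 4 s cycles: RR = 15 bpm, all SDs zero
  m <- compute_metrics(mk(rep(4, 15)), discard = 0)
  expect_equal(m$n_cycles, 15)
  expect_equal(m$mean[["RR"]], 15)
  expect_true(all(m$sd == 0))
  # I:E is T_e / T_i by definition
  m2 <- compute_metrics(mk(rep(3, 5), T_i = 1, T_e = 2), discard = 0)
  expect_equal(m2$mean[["IE_ratio"]], 2)
  # sample SD over {3,4,5}
  m3 <- compute_metrics(mk(c(3, 4, 5)), discard = 0)
  expect_equal(m3$mean[["period"]], 4)
  expect_equal(m3$sd[["period"]], 1)
  # RR_mean consistent with 60 / period_mean for near-constant periods
  expect_equal(m$mean[["RR"]], 60 / m$mean[["period"]])
})

test_that("insufficient data is reported as such", {
  spec <- fixture_spec(n_cycles = 1)
  expect_error(segment_breaths(make_synthetic_waveform(spec)),
               class = "oscvent_insufficient_data")
  cyc <- segment_breaths(make_synthetic_waveform(fixture_spec(n_cycles = 4)))
  expect_error(compute_metrics(cyc, discard = 10),
               class = "oscvent_insufficient_data")
  expect_error(fit_period_vs_depth(data.frame(d_EC = c(0, 1),
                                              period = c(3, 5))),
               class = "oscvent_insufficient_data")
})

test_that("metrics are invariant to a uniform time shift", {
  rec <- make_synthetic_waveform(fixture_spec(n_cycles = 6))
  shifted <- rec
  shifted$t <- shifted$t + 13.7
  m0 <- compute_metrics(segment_breaths(rec), discard = 1)
  m1 <- compute_metrics(segment_breaths(shifted), discard = 1)
  expect_equal(m0$mean, m1$mean)
  expect_equal(m0$sd, m1$sd)
})

test_that("collinear sweep rows are fitted exactly", {
  d <- seq(0, 1, by = 0.25)
  fit <- fit_period_vs_depth(data.frame(d_EC = d, period = 3 + 2 * d))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r_squared, 1)
})

test_that("noisy bench-like fixtures are recovered within 3 sigma", {
  spec <- fixture_spec(PIP = 17.15, PEEP = 11.66, T_i = 1, T_e = 3,
                       n_cycles = 15, noise_sd = 0.37, seed = 11)
  rec <- make_synthetic_waveform(spec)
  m <- compute_metrics(segment_breaths(data.frame(t = rec$t,
                                                  P_alv = rec$P_alv)),
                       discard = 2)
  expect_lt(abs(m$mean[["PEEP"]] - 11.66), 3 * 0.37)
  expect_lt(abs(m$mean[["PIP"]] - 17.15), 3 * 0.37)
  expect_lt(abs(m$mean[["period"]] - 4), 0.25)
})

test_that("EC sweep runs per setting with everything else fixed", {
  base <- quick_config(duration = 25)
  tab <- ec_sweep(base, c(0, 0.5, 1))
  expect_s3_class(tab, "ec_sweep")
  expect_equal(tab$d_EC, c(0, 0.5, 1))
  expect_true(all(diff(tab$period) > 0))
  expect_error(ec_sweep(base, c(-0.1, 0.5)), "\\[0, 1\\]")
  fit <- fit_period_vs_depth(tab)
  expect_gt(fit$slope, 0)
})
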