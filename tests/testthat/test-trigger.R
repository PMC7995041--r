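test_that("pleural pressure follows the first-order effort step", {
  sch <- trigger_schedule(enabled = TRUE, tau_s = 0.09)
  expect_equal(pleural_pressure(5, effort_start = 5, schedule = sch), 0)
  # one time constant into the effort
  expect_equal(pleural_pressure(5.09, effort_start = 5, schedule = sch),
               -3 * (1 - exp(-1)))
  # asymptote is the full step magnitude
  expect_equal(pleural_pressure(50, effort_start = 5, schedule = sch), -3,
               tolerance = 1e-9)
  # inactive -> identically zero
  expect_equal(pleural_pressure(c(0, 1, 2), NA, sch), c(0, 0, 0))
})

test_that("effort is monotone nonincreasing and bounded in (-A, 0]", {
  sch <- trigger_schedule(enabled = TRUE, amplitude_cmH2O = 3, tau_s = 0.2)
  t <- seq(1, 8, by = 0.01)
  p <- pleural_pressure(t, effort_start = 1, schedule = sch)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p <= 0 & p > -3))
})

test_that("trigger profiles and schedule validation", {
  expect_equal(trigger_schedule(profile = "insilico")$amplitude_cmH2O, 3)
  expect_equal(trigger_schedule(profile = "bench")$amplitude_cmH2O, 5.5)
  expect_error(trigger_schedule(times_s = c(2, 1)), "strictly increasing")
  expect_error(trigger_schedule(interval_s = 0), "interval_s")
  expect_error(pleural_pressure(1, 0, trigger_schedule(enabled = TRUE)),
               "time constant")
})

test_that("an effort late in expiration forces a premature inspiration", {
  base <- quick_config(duration = 25)
  rec0 <- simulate_ventilator(base)
  cyc0 <- segment_breaths(rec0)
  te_ss <- median(cyc0$T_e[-1])
  # schedule the effort when the untriggered run sits inside the trigger
  # band 8 < P_alv < 11, shortly before the natural switch
  sw <- attr(rec0, "switch_times")
  exp_start <- sw$time[sw$new_phase == "EXPIRATION"][3]
  seg <- rec0[rec0$t > exp_start & rec0$phase == "EXPIRATION" &
                rec0$t < exp_start + te_ss, ]
  t_eff <- seg$t[which(seg$P_alv <= 9.5)[1]]
  cfg_t <- quick_config(duration = 25,
                        trigger = trigger_schedule(enabled = TRUE,
                                                   times_s = t_eff))
  cyc_t <- segment_breaths(simulate_ventilator(cfg_t))
  k <- which(cyc_t$triggered)[1]
  expect_false(is.na(k))
  expect_lt(cyc_t$T_e[k], te_ss - 0.1)
})

test_that("the cycle after an in-band trigger keeps PIP, PEEP and period within 5%", {
  base <- quick_config(duration = 30)
  rec0 <- simulate_ventilator(base)
  m0 <- compute_metrics(segment_breaths(rec0), discard = 2)
  sw <- attr(rec0, "switch_times")
  exp_start <- sw$time[sw$new_phase == "EXPIRATION"][3]
  seg <- rec0[rec0$t > exp_start & rec0$phase == "EXPIRATION", ]
  for (p_onset in c(10, 9, 8.5)) {
    t_eff <- seg$t[which(seg$P_alv <= p_onset)[1]]
    cfg_t <- quick_config(duration = 30,
                          trigger = trigger_schedule(enabled = TRUE,
                                                     times_s = t_eff))
    cyc_t <- segment_breaths(simulate_ventilator(cfg_t))
    k <- which(cyc_t$triggered)[1]
    post <- cyc_t[k + 1, ]
    expect_lt(abs(post$PIP - m0$mean[["PIP"]]) / m0$mean[["PIP"]], 0.05)
    expect_lt(abs(post$PEEP - m0$mean[["PEEP"]]) / m0$mean[["PEEP"]], 0.05)
    expect_lt(abs(post$period - m0$mean[["period"]]) / m0$mean[["period"]],
              0.05)
  }
})

test_that("efforts scheduled during inspiration are skipped, not queued", {
  base <- quick_config(duration = 20)
  rec0 <- simulate_ventilator(base)
  sw <- attr(rec0, "switch_times")
  # midpoint of an inspiration of the untriggered run
  insp_start <- sw$time[sw$new_phase == "INSPIRATION"][2]
  exp_next <- sw$time[sw$new_phase == "EXPIRATION" & sw$time > insp_start][1]
  t_eff <- (insp_start + exp_next) / 2
  cfg_t <- quick_config(duration = 20,
                        trigger = trigger_schedule(enabled = TRUE,
                                                   times_s = t_eff))
  rec_t <- simulate_ventilator(cfg_t)
  # no effort ever develops and the record matches the passive run
  expect_true(all(rec_t$P_pl == 0))
  expect_identical(rec_t$P_alv, rec0$P_alv)
})
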