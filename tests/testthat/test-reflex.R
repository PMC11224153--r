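# Baroreflex sensor, effector dynamics and parameter application.

test_that("sensor is a first-order low-pass of arterial pressure", {
  cfg <- reflex_config(sensor_tau = 2)
  st <- reflex_state(p_sensed = 100)
  # one small Euler step toward 110: increase ~ dt/tau * 10
  st1 <- reflex_sense(110, st, cfg, dt = 1e-3)
  expect_equal(st1$p_sensed - 100, 1e-3 / 2 * 10, tolerance = 1e-9)
  # held input converges to the input for t >> tau
  for (i in 1:20000) st <- reflex_sense(110, st, cfg, dt = 1e-3)
  expect_equal(st$p_sensed, 110, tolerance = 1e-3)
  # a near-infinite time constant freezes the sensor
  cfg2 <- reflex_config(sensor_tau = 1e12)
  st2 <- reflex_sense(200, reflex_state(p_sensed = 95), cfg2, dt = 1)
  expect_equal(st2$p_sensed, 95, tolerance = 1e-9)
})

test_that("effectors settle at the saturated proportional steady state", {
  cfg <- reflex_config(set_point = 100,
                       gains = c(hr = 0.02, emax = 0.02, r = 0.02,
                                 vu = 0.02),
                       lo = c(hr = 0.5, emax = 0.5, r = 0.5, vu = 0.5),
                       hi = c(hr = 2, emax = 2, r = 2, vu = 2))
  st <- reflex_state(p_sensed = 90)   # 10 mmHg below set point
  for (i in 1:80000) st <- reflex_effectors(st, cfg, dt = 1e-2)
  # steady state of the linear law: 1 + 0.02 * 10 = 1.2 for hr/emax/r
  expect_equal(unname(st$mult[c("hr", "emax", "r")]), rep(1.2, 3),
               tolerance = 1e-6)
  # the venous-tone effector has the opposite sign
  expect_equal(unname(st$mult[["vu"]]), 0.8, tolerance = 1e-6)
  # at the set point every multiplier returns to 1
  st$p_sensed <- 100
  for (i in 1:80000) st <- reflex_effectors(st, cfg, dt = 1e-2)
  expect_equal(unname(st$mult), rep(1, 4), tolerance = 1e-6)
})

test_that("zero gains give an open-loop model", {
  cfg <- reflex_config(gains = c(hr = 0, emax = 0, r = 0, vu = 0))
  st <- reflex_state(p_sensed = 60)
  for (i in 1:1000) st <- reflex_effectors(st, cfg, dt = 0.1)
  expect_equal(unname(st$mult), rep(1, 4))
})

test_that("saturation bounds clamp the effector targets", {
  cfg <- reflex_config(set_point = 100,
                       gains = c(hr = 0.1, emax = 0.1, r = 0.1, vu = 0.1),
                       lo = c(hr = 0.6, emax = 0.6, r = 0.6, vu = 0.6),
                       hi = c(hr = 1.5, emax = 1.5, r = 1.5, vu = 1.5))
  st <- reflex_state(p_sensed = 40)   # huge error, would give 7 unclamped
  for (i in 1:50000) st <- reflex_effectors(st, cfg, dt = 1e-2)
  expect_equal(unname(st$mult[c("hr", "emax", "r")]), rep(1.5, 3),
               tolerance = 1e-6)
  expect_equal(unname(st$mult[["vu"]]), 0.6, tolerance = 1e-6)
})

test_that("hypotension monotonically drives the effector signs", {
  cfg <- reflex_config(set_point = 95)
  st <- reflex_state(p_sensed = 95)
  mh <- mr <- mv <- 1
  for (i in 1:500) {
    st <- reflex_sense(70, st, cfg, dt = 0.05)   # pressure step down
    st <- reflex_effectors(st, cfg, dt = 0.05)
    expect_gte(st$mult[["hr"]], mh - 1e-12)
    expect_gte(st$mult[["r"]], mr - 1e-12)
    expect_lte(st$mult[["vu"]], mv + 1e-12)
    mh <- st$mult[["hr"]]; mr <- st$mult[["r"]]; mv <- st$mult[["vu"]]
  }
  expect_gt(mh, 1); expect_gt(mr, 1); expect_lt(mv, 1)
})

test_that("apply_effectors scales parameters without mutating the model", {
  m <- default_model()
  st <- reflex_state(mult = c(hr = 1.2, emax = 1.1, r = 1.3, vu = 0.9))
  eff <- apply_effectors(m, st)
  expect_equal(eff$hr, m$globals$hr0 * 1.2)
  lv_emax <- m$compartments$emax[m$compartments$name == "lv"]
  expect_equal(unname(eff$emax[["lv"]]), lv_emax * 1.1)
  ctl <- m$compartments$vu_ctl
  expect_equal(unname(eff$vu), m$compartments$vu[ctl] * 0.9)
  expect_equal(unname(eff$r),
               m$edges$R[m$edges$r_ctl] * 1.3)
  # identity multipliers reproduce the base parameters exactly
  eff1 <- apply_effectors(m, reflex_state())
  expect_equal(eff1$hr, m$globals$hr0)
  expect_equal(unname(eff1$r), m$edges$R[m$edges$r_ctl])
  # base model untouched
  expect_equal(m$compartments$emax[m$compartments$name == "lv"], lv_emax)
})

test_that("open-loop transition deviates more from baseline than closed", {
  closed <- transition_sim("normal")
  open <- cached_sim("trans_open", function()
    simulate_model(scenario_model("normal"),
                   microgravity_protocol("standing"), dt = 5e-4,
                   open_loop = TRUE))
  dev_c <- abs(beat_metrics(closed, 225)$map - beat_metrics(closed, 80)$map)
  dev_o <- abs(beat_metrics(open, 225)$map - beat_metrics(open, 80)$map)
  # the reflex demonstrably conserves pressure across the transition
  expect_lt(dev_c, dev_o)
})
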