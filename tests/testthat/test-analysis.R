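# Beat-averaged metrics, PV loops, coupling and risk flags.

test_that("beat metrics recover analytic values from a sinusoidal beat", {
  sim <- synthetic_sim(hr = 60, map = 100, amp = 20)
  bm <- beat_metrics(sim, 3)
  expect_equal(bm$map, 100, tolerance = 1e-3)
  expect_equal(bm$sap, 120, tolerance = 1e-3)
  expect_equal(bm$dap, 80, tolerance = 1e-3)
  expect_equal(bm$hr, 60)
  expect_equal(bm$lvedv, 135, tolerance = 1e-3)
  expect_equal(bm$lvesv, 65, tolerance = 1e-3)
  expect_equal(bm$sv, 70, tolerance = 1e-3)
  expect_equal(bm$ef, 100 * 70 / 135, tolerance = 1e-3)
  expect_equal(bm$co, 70 * 60 / 1000, tolerance = 1e-3)
  expect_equal(bm$lap, 8); expect_equal(bm$rap, 2)
  # Ea from peak LV pressure over stroke volume; Ees is the profile Emax
  expect_equal(bm$ea, 120 / 70, tolerance = 1e-3)
  expect_equal(bm$ea_ees, 120 / 70 / 2.5, tolerance = 1e-3)
})

test_that("a degenerate constant pressure trace gives SAP = DAP = MAP", {
  sim <- synthetic_sim(amp = 0)
  bm <- beat_metrics(sim, 2)
  expect_equal(bm$sap, bm$map)
  expect_equal(bm$dap, bm$map)
})

test_that("beat metrics error without a complete beat", {
  sim <- synthetic_sim(hr = 60, n_beats = 3)
  expect_error(beat_metrics(sim, 0.5), "complete beat")
})

test_that("arterial elastance is ESP/SV and guards zero stroke volume", {
  cpl <- arterial_elastance(100, 50, 2)
  expect_equal(cpl$ea, 2)
  expect_equal(cpl$ea_ees, 1)
  expect_error(arterial_elastance(100, 0, 2), "stroke volume")
})

test_that("internal consistency: CO equals HR * SV on simulated beats", {
  for (prof in c("normal", "hfref")) {
    sim <- if (prof == "normal") supine_sim("normal") else
      transition_sim("hfref")
    for (tt in c(60, 80)) {
      bm <- beat_metrics(sim, tt)
      expect_lt(abs(bm$co - bm$hr * bm$sv / 1000), 0.1)
      expect_true(bm$sap >= bm$map && bm$map >= bm$dap)
      expect_true(bm$lvedv >= bm$lvesv && bm$lvesv >= 0)
      expect_true(bm$ef >= 0 && bm$ef <= 100)
    }
  }
})

test_that("PV loop closes and its shoelace area matches trapezoid P dV", {
  sim <- supine_sim("normal")
  loop <- extract_pv_loop(sim, 80)
  # closure: first and last point within one output stride's volume change
  dv_max <- max(abs(diff(loop$v)))
  expect_lt(abs(loop$v[1] - loop$v[nrow(loop)]), dv_max * 2 + 1e-9)
  a_shoe <- loop_area(loop)
  # independent oracle: -cyclic trapezoid integral of P dV
  v <- c(loop$v, loop$v[1]); p <- c(loop$p, loop$p[1])
  a_trap <- -sum(diff(v) * (head(p, -1) + tail(p, -1)) / 2)
  expect_equal(a_shoe, a_trap, tolerance = 0.005)
  # counterclockwise orientation: positive stroke work
  expect_gt(a_shoe, 0)
})

test_that("transition report deltas are exactly post minus pre", {
  sim <- transition_sim("normal")
  rep <- transition_report(sim)
  for (f in names(rep$delta))
    expect_equal(rep$delta[[f]], rep$post[[f]] - rep$pre[[f]])
  expect_gt(rep$spike_lap_peak, rep$post$lap * 0.95)
  expect_gt(rep$spike_duration, 0)
})

test_that("a steady protocol yields near-zero deltas", {
  m <- default_model()
  segs <- data.frame(t_start = 0, g_level = 1, posture = "supine",
                     shift = 0, ramp = 0)
  prot <- protocol(segs, sample_times = c(pre = 60, post = 85),
                   duration = 90)
  sim <- cached_sim("null_protocol", function()
    simulate_model(m, prot, dt = 5e-4))
  rep <- transition_report(sim)
  expect_lt(abs(rep$delta$lap), 0.1)
  expect_lt(abs(rep$delta$co), 0.1)
  expect_lt(abs(rep$delta$map), 1)
})

test_that("risk flags follow the LAP and cardiac index thresholds", {
  fake <- function(post_lap, pre_co = 5, post_co = 5.5) {
    structure(list(pre = data.frame(co = pre_co, lap = 5),
                   post = data.frame(co = post_co, lap = post_lap),
                   delta = data.frame(lap = post_lap - 5)),
              class = "cp_transition_report")
  }
  expect_identical(risk_flags(fake(26)), "pulmonary_oedema_risk")
  # moderately elevated: chronic concern, not the acute flag
  expect_identical(risk_flags(fake(22)), "chronic_lap_elevation")
  expect_identical(risk_flags(fake(8)), character(0))
  # cardiac index below 1.8 L/min/m^2 with an explicit BSA
  expect_identical(risk_flags(fake(8, pre_co = 2.0), bsa = 1.31),
                   "cardiogenic_shock_risk")
  # CI 2.64/1.31 = 2.01: no shock flag
  expect_identical(risk_flags(fake(8, pre_co = 2.64), bsa = 1.31),
                   character(0))
})
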