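# Pressure, elastance and flow laws of the compartment circuit.

test_that("time-varying elastance spans Emin..Emax with the right shape", {
  sf <- 0.3
  expect_equal(varying_elastance(0, 0.1, 2.5, sf), 0.1)
  # squared half-sine: the activation peak sits at half the systolic window
  expect_equal(varying_elastance(sf / 2, 0.1, 2.5, sf), 2.5)
  ph <- seq(0, 1 - 1e-9, length.out = 4001)
  e <- varying_elastance(ph, 0.1, 2.5, sf)
  expect_equal(max(e), 2.5, tolerance = 1e-6)
  expect_true(all(e >= 0.1 - 1e-12))
  # diastole is flat at Emin for phase >= systolic fraction
  expect_true(all(e[ph >= sf] == 0.1))
  # periodicity: E(0) == E(1-) == Emin to machine precision
  expect_equal(varying_elastance(1 - 1e-12, 0.1, 2.5, sf), 0.1)
  expect_equal(varying_elastance(1, 0.1, 2.5, sf),
               varying_elastance(0, 0.1, 2.5, sf))
  # continuity across the systole/diastole joint
  expect_lt(abs(varying_elastance(sf - 1e-9, 0.1, 2.5, sf) - 0.1), 1e-6)
  expect_error(varying_elastance(0.1, 2.5, 0.1, sf), "emax")
  expect_error(varying_elastance(0.1, 0.1, 2.5, 1.2), "systolic_fraction")
})

test_that("compartment pressure follows the elastance/thoracic/gravity law", {
  gl <- global_params(p_intrathoracic = -4, density_factor = 0.77,
                      g_level = 1)
  vasc <- compartment_spec("x", "vascular", E = 1, vu = 100)
  expect_equal(compartment_pressure(120, vasc, globals = gl,
                                    posture_scale = 0), 20)
  thor <- compartment_spec("x", "vascular", E = 1, vu = 100, thoracic = TRUE)
  # zero stressed volume leaves only the intrathoracic term
  expect_equal(compartment_pressure(100, thor, globals = gl,
                                    posture_scale = 0), -4)
  # elastic clamp: no suction below the unstressed volume
  expect_equal(compartment_pressure(60, thor, globals = gl,
                                    posture_scale = 0), -4)
  # hydrostatic head term: rho * g * h with 0.77 mmHg per cm of blood;
  # 50 cm below heart level shifts the head by -0.77 * 50 = -38.5, so the
  # luminal (elastic) pressure of a dependent compartment in equilibrium
  # exceeds a heart-level one's by +38.5
  leg <- compartment_spec("leg", "vascular", E = 1, vu = 100, height = -50)
  expect_equal(compartment_pressure(120, leg, globals = gl,
                                    posture_scale = 1), 20 - 38.5)
  # supine or 0 G zeroes the hydrostatic term
  expect_equal(compartment_pressure(120, leg, globals = gl,
                                    posture_scale = 0), 20)
  expect_error(compartment_pressure(-1, vasc, globals = gl), "negative")
  card <- compartment_spec("lv", "cardiac", emin = 0.1, emax = 2.5, vu = 10)
  expect_error(compartment_pressure(100, card, globals = gl), "e_now")
  expect_equal(compartment_pressure(100, card, e_now = 2, globals = gl,
                                    posture_scale = 0), 180)
})

test_that("edge flow is linear with ideal diode valves", {
  expect_equal(edge_flow(10, 5, 1), 5)
  expect_equal(edge_flow(5, 10, 1, valved = TRUE), 0)
  expect_equal(edge_flow(7, 7, 2), 0)
  expect_equal(edge_flow(7, 7, 2, valved = TRUE), 0)
  expect_equal(edge_flow(5, 10, 2), -2.5)
  expect_error(edge_flow(1, 0, 0), "positive")
  expect_error(edge_flow(1, 0, -1), "positive")
})

test_that("lymphatic return is one-way and proportional", {
  expect_equal(lymphatic_flow(8, 3, 0.01), 0.05)
  expect_equal(lymphatic_flow(3, 8, 0.01), 0)
  expect_equal(lymphatic_flow(50, -50, 0), 0)
  expect_error(lymphatic_flow(1, 0, -0.1), ">= 0")
})

test_that("compartment and model constructors enforce their invariants", {
  expect_error(compartment_spec("x", "vascular", E = -1), "E > 0")
  expect_error(compartment_spec("x", "cardiac", emin = 0.5, emax = 0.1),
               "Emax >= Emin")
  expect_error(compartment_spec("x", "vascular", E = 1, vu = -5), ">= 0")
  expect_error(compartment_spec("x", "cardiac", emin = 0.1, emax = 1, E = 2),
               "emin/emax")
  m <- default_model()
  expect_s3_class(m, "cp_model")
  expect_identical(nrow(m$compartments), 21L)
  expect_identical(sum(m$compartments$kind == "cardiac"), 4L)
  # dropping an edge breaks the closed-circulation invariant
  e2 <- m$edges[m$edges$from != "la", ]
  expect_error(build_model(m$compartments, e2, m$lymph, m$globals, m$reflex),
               "cardiac chain|closed circulation")
})

test_that("parameter tables round-trip through CSV with schema checks", {
  m <- default_model()
  f <- tempfile(fileext = ".csv")
  write_param_table(m$compartments, f)
  back <- read_param_table(f)
  expect_equal(back, m$compartments, tolerance = 1e-12)
  bad <- m$compartments
  bad$mystery <- 1
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_param_table(f2), "unknown column")
})
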