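# Literature pooling, disease profiles, countermeasure and calibration.

test_that("sample-size-weighted pooling matches direct arithmetic", {
  expect_equal(weighted_mean_n(c(1, 3), c(1, 1)), 2)
  expect_equal(weighted_mean_n(5.5, 37), 5.5)
  expect_equal(weighted_mean_n(c(2, 3), c(30, 10)), 2.25)
  expect_error(weighted_mean_n(numeric(0), numeric(0)), "no study")
  expect_error(weighted_mean_n(c(1, 2), 1), "length")
  expect_error(weighted_mean_n(c(1, 2), c(1, 0.5)), ">= 1")
})

test_that("pooled values always lie within the range of the studies", {
  set.seed(7)
  for (i in 1:25) {
    v <- rnorm(sample(2:8, 1), 100, 30)
    n <- sample(1:500, length(v), replace = TRUE)
    p <- weighted_mean_n(v, n)
    expect_gte(p, min(v)); expect_lte(p, max(v))
  }
})

test_that("HFrEF substitution touches only the prescribed parameters", {
  m <- default_model()
  h <- apply_hfref(m)
  i_lv <- match("lv", m$compartments$name)
  expect_equal(h$compartments$emax[i_lv], 0.99)
  expect_equal(h$compartments$emin[i_lv], 0.10)
  expect_gt(h$compartments$vu[i_lv], m$compartments$vu[i_lv])
  # profile locality: a diff of the tables has exactly the expected entries
  diff <- which(as.matrix(h$compartments[, c("E", "emin", "emax", "vu")]) !=
                  as.matrix(m$compartments[, c("E", "emin", "emax", "vu")]),
                arr.ind = TRUE)
  expect_equal(unname(diff[, "row"]), c(i_lv, i_lv))
  expect_identical(h$edges, m$edges)
  expect_identical(h$reflex, m$reflex)
  expect_identical(h$globals, m$globals)
  expect_identical(attr(h, "profile"), "hfref")
})

test_that("HFpEF substitution stiffens diastole and dilates the atrium", {
  m <- default_model()
  p <- apply_hfpef(m)
  i_lv <- match("lv", m$compartments$name)
  i_la <- match("la", m$compartments$name)
  expect_equal(p$compartments$emin[i_lv], 0.21)
  expect_equal(p$compartments$emax[i_lv], 2.50)
  expect_equal(p$compartments$vu[i_la],
               m$compartments$vu[i_la] * 53.6 / 32.1)
  expect_identical(attr(p, "profile"), "hfpef")
})

test_that("profiles are not composable and warn on uncalibrated tables", {
  m <- default_model()
  h <- apply_hfref(m)
  expect_error(apply_hfpef(h), "not composable")
  expect_error(apply_hfref(h), "not composable")
  attr(m, "calibrated") <- FALSE
  expect_warning(apply_hfpef(m), "uncalibrated")
})

test_that("the countermeasure scales blood volume and initial volumes", {
  m <- default_model()
  m$globals$total_blood_volume <- 5000
  c1 <- apply_countermeasure(m, 0.09)
  expect_equal(c1$globals$total_blood_volume, 4550)
  c0 <- apply_countermeasure(m, 0)
  expect_equal(c0$globals$total_blood_volume, 5000)
  expect_error(apply_countermeasure(m, 1), "fraction")
  expect_error(apply_countermeasure(m, -0.1), "fraction")
  # initial stressed volumes shrink proportionally, unstressed floor intact
  v_full <- distribute_volumes(m)
  v_cm <- distribute_volumes(c1)
  vu <- setNames(m$compartments$vu, m$compartments$name)
  expect_equal(unname((v_cm - vu) / (v_full - vu)),
               rep((4550 - sum(vu)) / (5000 - sum(vu)), 21))
})

test_that("the shipped table is a fixed point of calibration", {
  cal <- cached_sim("calibration", function()
    calibrate_baseline(default_model(), dt = 5e-4))
  expect_true(cal$converged)
  expect_identical(cal$iterations, 0L)
  expect_true(all(abs(cal$residuals) < 0.10))
  expect_named(cal$residuals)
  expect_length(cal$residuals, 15)
})

test_that("HF profiles change supine hemodynamics in the reported directions", {
  bn <- beat_metrics(supine_sim("normal"), 80)
  bh <- beat_metrics(supine_sim("hfref"), 80)
  bp <- beat_metrics(supine_sim("hfpef"), 80)
  # left atrial pressure rises in both HF phenotypes
  expect_gt(bh$lap, bn$lap)
  expect_gt(bp$lap, bn$lap)
  # EF collapses below 40% in HFrEF only
  expect_lt(bh$ef, 40)
  expect_gt(bp$ef, 40)
  expect_gt(bn$ef, 40)
  # ventriculo-arterial uncoupling (Ea/Ees > 1.5) in HFrEF only
  expect_gt(bh$ea_ees, 1.5)
  expect_lt(bp$ea_ees, 1.5)
  expect_lt(bn$ea_ees, 1.5)
})

test_that("volume reduction lowers pre-flight CO and LAP in heart failure", {
  for (prof in c("hfref", "hfpef")) {
    r0 <- transition_report(transition_sim(prof))
    r1 <- transition_report(transition_sim(prof, countermeasure = TRUE))
    expect_lt(r1$pre$co, r0$pre$co)
    expect_lt(r1$pre$lap, r0$pre$lap)
    expect_lt(r1$post$lap, r0$post$lap)
  }
})
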