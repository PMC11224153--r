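# Shared fixtures: the shipped scenarios are expensive to integrate, so
# each configuration is simulated at most once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

scenario_model <- function(profile = "normal", countermeasure = FALSE) {
  m <- default_model()
  m <- switch(profile, normal = m, hfref = apply_hfref(m),
              hfpef = apply_hfpef(m))
  if (countermeasure) m <- apply_countermeasure(m, 0.09)
  m
}

# supine-1G baseline run of a profile (production step size)
supine_sim <- function(profile = "normal") {
  cached_sim(paste0("supine_", profile), function()
    simulate_model(scenario_model(profile), supine_baseline_protocol()))
}

# standing-1G -> 0G transition run of a profile
transition_sim <- function(profile = "normal", countermeasure = FALSE) {
  key <- paste0("trans_", profile, if (countermeasure) "_cm" else "")
  cached_sim(key, function()
    simulate_model(scenario_model(profile, countermeasure),
                   microgravity_protocol("standing")))
}

# a tiny passive two-compartment model useful for fast integration tests
fast_toy_sim <- function(n = 1, seed = 1, duration = 20, dt = 1e-3) {
  toy <- toy_circuit(n, seed)
  prot <- protocol(data.frame(t_start = 0, g_level = 0, posture = "supine",
                              shift = 0, ramp = 0),
                   sample_times = c(pre = duration / 2),
                   duration = duration)
  list(toy = toy,
       sim = simulate_model(toy$model, prot, dt = dt,
                            init_volumes = toy$init))
}

# minimal hand-built cp_sim carrying analytic waveforms, for analysis tests
synthetic_sim <- function(hr = 60, n_beats = 3, stride = 1e-3,
                          map = 100, amp = 20, lv_emax = 2.5) {
  tb <- 60 / hr
  t <- seq(0, n_beats * tb, by = stride)
  pao <- map + amp * sin(2 * pi * t / tb)
  vlv <- 100 - 35 * sin(2 * pi * t / tb)   # 65..135 mL
  plv <- pao - 2
  comp <- rbind(
    compartment_spec("lv", "cardiac", emin = 0.1, emax = lv_emax, vu = 10),
    compartment_spec("ao_th", "vascular", E = 1),
    compartment_spec("la", "cardiac", emin = 0.3, emax = 0.5, atrial = TRUE),
    compartment_spec("ra", "cardiac", emin = 0.2, emax = 0.4, atrial = TRUE))
  P <- cbind(ao_th = pao, la = 0 * t + 8, ra = 0 * t + 2, lv = plv)
  V <- cbind(lv = vlv, ao_th = t * 0, la = t * 0 + 50, ra = t * 0 + 50)
  structure(list(time = t, P = P, V = V,
                 beats = seq(0, n_beats) * tb,
                 model = list(compartments = comp),
                 dt = stride, output_stride = stride),
            class = "cp_sim")
}
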