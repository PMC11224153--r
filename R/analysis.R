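# Reduction of simulated time series to beat-averaged hemodynamics,
# pressure-volume loops, ventriculo-arterial coupling and transition
# summaries.

# indices of the recorded samples spanning the last complete beat ending at
# or before sample_t; returns list(idx, t0, t1)
last_beat_window <- function(sim, sample_t) {
  b <- sim$beats[sim$beats <= sample_t + 1e-9]
  if (length(b) < 2)
    stop("no complete beat before t = ", sample_t, " s")
  t0 <- b[length(b) - 1]; t1 <- b[length(b)]
  idx <- which(sim$time >= t0 - 1e-9 & sim$time <= t1 + 1e-9)
  if (length(idx) < 5) stop("output stride too coarse to resolve a beat")
  list(idx = idx, t0 = t0, t1 = t1)
}

#' Arterial elastance and ventriculo-arterial coupling
#'
#' `Ea = ESP / SV`, with the end-systolic pressure taken as the systolic
#' (peak) aortic pressure of the beat -- the standard non-invasive Ea
#' approximation, identical to peak LV pressure up to the small gradient
#' across an ideal aortic valve -- and `Ea/Ees` with `Ees` the scenario's
#' (static) left ventricular end-systolic elastance.
#'
#' @param esp end-systolic LV pressure, mmHg.
#' @param sv stroke volume, mL (> 0).
#' @param ees scenario LV end-systolic elastance (`Emax`), mmHg/mL.
#' @return list with `ea` and `ea_ees`.
#' @export
arterial_elastance <- function(esp, sv, ees) {
  if (sv <= 0) stop("stroke volume must be positive to define Ea")
  ea <- esp / sv
  list(ea = ea, ea_ees = ea / ees)
}

#' Beat-averaged hemodynamic metrics
#'
#' Summarizes the last complete beat ending at or before `sample_t`:
#' mean/systolic/diastolic aortic pressure, beat-averaged atrial pressures,
#' LV end-diastolic and end-systolic volume, stroke volume, ejection
#' fraction, cardiac output, heart rate (from the beat length), arterial
#' elastance and ventriculo-arterial coupling.
#'
#' @param sim a `cp_sim` of the full 21-compartment model.
#' @param sample_t sampling time, s.
#' @return one-row `data.frame` of class `cp_beat_metrics` with columns
#'   `co` (L/min), `hr` (bpm), `map`, `sap`, `dap`, `lap`, `rap` (mmHg),
#'   `lvedv`, `lvesv`, `sv` (mL), `ef` (%), `ea` (mmHg/mL), `ea_ees`,
#'   and the beat window `t0`, `t1`.
#' @export
beat_metrics <- function(sim, sample_t) {
  w <- last_beat_window(sim, sample_t)
  tt <- sim$time[w$idx]
  span <- max(tt) - min(tt)
  pao <- sim$P[w$idx, "ao_th"]
  vlv <- sim$V[w$idx, "lv"]
  plv <- sim$P[w$idx, "lv"]
  hr <- 60 / (w$t1 - w$t0)
  lvedv <- max(vlv); lvesv <- min(vlv)
  sv <- lvedv - lvesv
  esp <- max(pao)
  ees <- sim$model$compartments$emax[match("lv", sim$model$compartments$name)]
  cpl <- arterial_elastance(esp, sv, ees)
  out <- data.frame(
    co = sv * hr / 1000,
    hr = hr,
    map = trapz(tt, pao) / span,
    sap = max(pao),
    dap = min(pao),
    lap = trapz(tt, sim$P[w$idx, "la"]) / span,
    rap = trapz(tt, sim$P[w$idx, "ra"]) / span,
    lvedv = lvedv, lvesv = lvesv, sv = sv,
    ef = 100 * sv / lvedv,
    ea = cpl$ea, ea_ees = cpl$ea_ees,
    t0 = w$t0, t1 = w$t1)
  class(out) <- c("cp_beat_metrics", "data.frame")
  out
}

#' @export
print.cp_beat_metrics <- function(x, digits = 3, ...) {
  cat(sprintf(
    "beat %.2f-%.2f s: CO %.1f L/min | HR %.0f bpm | MAP %.0f (SAP %.0f / DAP %.0f) mmHg\n",
    x$t0, x$t1, x$co, x$hr, x$map, x$sap, x$dap))
  cat(sprintf(
    "  LAP %.1f / RAP %.1f mmHg | LVEDV %.0f / LVESV %.0f mL | EF %.0f%% | Ea %.2f | Ea/Ees %.2f\n",
    x$lap, x$rap, x$lvedv, x$lvesv, x$ef, x$ea, x$ea_ees))
  invisible(x)
}

#' Extract the left ventricular pressure-volume loop
#'
#' The (volume, pressure) trace of the LV over the last complete beat
#' before `sample_t`.  The signed shoelace area of the loop equals the
#' stroke work and is positive for the physiological counterclockwise
#' orientation in the (V, P) plane.
#'
#' @inheritParams beat_metrics
#' @return `data.frame` of class `cp_pv_loop` with columns `t`, `v`, `p`.
#' @export
extract_pv_loop <- function(sim, sample_t) {
  w <- last_beat_window(sim, sample_t)
  out <- data.frame(t = sim$time[w$idx], v = sim$V[w$idx, "lv"],
                    p = sim$P[w$idx, "lv"])
  class(out) <- c("cp_pv_loop", "data.frame")
  attr(out, "scenario") <- attr(sim$model, "profile") %||% "normal"
  out
}

#' Stroke work from a PV loop
#'
#' Signed shoelace area of the closed loop, mmHg mL; equals the cyclic
#' integral of P dV.
#'
#' @param loop a [extract_pv_loop()] result.
#' @return area, mmHg mL.
#' @export
loop_area <- function(loop) {
  v <- c(loop$v, loop$v[1]); p <- c(loop$p, loop$p[1])
  n <- length(v)
  # shoelace in (V, P); positive when counterclockwise, i.e. ejection at
  # high pressure and filling at low pressure
  sum(v[-n] * p[-1] - v[-1] * p[-n]) / 2
}

#' Transition summary across a gravity protocol
#'
#' Beat metrics at the protocol's `pre` and `post` sample times, their
#' exact per-metric differences, and the left-atrial-pressure transient:
#' the peak beat-averaged LAP within 60 s of transition onset (the
#' envelope of the within-beat pressure waves, as plotted in beat-wise
#' transition traces) and the time until the beat-averaged LAP settles
#' into +/-10% of its post plateau.
#'
#' @param sim a `cp_sim` run under a protocol with `pre` and `post` sample
#'   times (see [microgravity_protocol()]).
#' @param prot the protocol; defaults to the one stored in the simulation.
#' @return list of class `cp_transition_report` with elements `pre`,
#'   `post`, `delta`, `spike_lap_peak` (mmHg) and `spike_duration` (s).
#' @export
transition_report <- function(sim, prot = sim$protocol) {
  st <- prot$sample_times
  if (!all(c("pre", "post") %in% names(st)))
    stop("protocol must define 'pre' and 'post' sample times")
  pre <- beat_metrics(sim, st[["pre"]])
  post <- beat_metrics(sim, st[["post"]])
  metric_cols <- setdiff(names(pre), c("t0", "t1"))
  delta <- post[metric_cols] - pre[metric_cols]
  # transition onset = first segment change after the pre sample
  seg_t <- prot$segments$t_start
  t_on <- seg_t[seg_t > st[["pre"]]][1]
  spike_peak <- NA_real_; spike_dur <- NA_real_
  if (is.finite(t_on)) {
    # beat-averaged LAP per beat after onset: the transient envelope
    bb <- sim$beats[sim$beats >= t_on]
    plateau <- post$lap
    lap_beat <- vapply(seq_len(length(bb) - 1), function(i) {
      idx <- sim$time >= bb[i] & sim$time <= bb[i + 1]
      mean(sim$P[idx, "la"])
    }, 0)
    in60 <- bb[-length(bb)] <= t_on + 60
    spike_peak <- max(lap_beat[in60])
    outside <- abs(lap_beat - plateau) > 0.1 * abs(plateau)
    spike_dur <- if (any(outside)) bb[max(which(outside)) + 1] - t_on else 0
  }
  structure(list(pre = pre, post = post, delta = delta,
                 spike_lap_peak = spike_peak, spike_duration = spike_dur,
                 scenario = attr(sim$model, "profile") %||% "normal"),
            class = "cp_transition_report")
}

#' @export
print.cp_transition_report <- function(x, ...) {
  cat("<cp_transition_report> scenario:", x$scenario, "\n")
  cat("pre : "); print(x$pre)
  cat("post: "); print(x$post)
  cat(sprintf("delta LAP %+.1f | RAP %+.1f | CO %+.1f | HR %+.0f\n",
              x$delta$lap, x$delta$rap, x$delta$co, x$delta$hr))
  cat(sprintf("LAP spike: peak %.1f mmHg, settles in %.0f s\n",
              x$spike_lap_peak, x$spike_duration))
  invisible(x)
}

#' Clinical risk flags from a transition report
#'
#' \itemize{
#'   \item `pulmonary_oedema_risk` when the post-transition plateau LAP
#'     reaches the acute threshold of 25 mmHg;
#'   \item `chronic_lap_elevation` when the post LAP stays below 25 mmHg
#'     but above the normal resting range (> 12 mmHg), a concern for
#'     prolonged exposure;
#'   \item `cardiogenic_shock_risk` when a body surface area is supplied
#'     and the cardiac index falls below 1.8 L/min/m^2.
#' }
#'
#' @param report a [transition_report()].
#' @param bsa optional body surface area, m^2; cardiac index is only
#'   computed when it is given explicitly.
#' @return character vector of flags (possibly empty).
#' @export
risk_flags <- function(report, bsa = NULL) {
  flags <- character()
  lap <- report$post$lap
  if (lap >= 25) flags <- c(flags, "pulmonary_oedema_risk")
  else if (lap > 12) flags <- c(flags, "chronic_lap_elevation")
  if (!is.null(bsa)) {
    ci <- min(report$pre$co, report$post$co) / bsa
    if (ci < 1.8) flags <- c(flags, "cardiogenic_shock_risk")
  }
  flags
}
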