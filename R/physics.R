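#' Time-varying chamber elastance
#'
#' Squared half-sine activation: the elastance rises from `emin` to `emax`
#' and falls back within the systolic fraction of the cycle, and stays at
#' `emin` for the rest of the beat.  `E(0) = E(1^-) = emin`, the maximum
#' over the cycle is `emax`, and the waveform is continuous and periodic.
#'
#' @param phase fraction of the cardiac cycle elapsed, in `[0, 1)` (values
#'   outside are wrapped).
#' @param emin,emax diastolic / end-systolic elastance, mmHg/mL.
#' @param systolic_fraction fraction of the cycle spent in systole,
#'   in (0, 1).
#' @return elastance at `phase`, mmHg/mL.
#' @export
varying_elastance <- function(phase, emin, emax, systolic_fraction = 0.33) {
  if (any(emax < emin)) stop("emax must be >= emin")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must lie in (0, 1)")
  ph <- phase - floor(phase)
  act <- ifelse(ph < systolic_fraction,
                sin(pi * ph / systolic_fraction)^2, 0)
  emin + (emax - emin) * act
}

#' Compartment pressure (piezometric head)
#'
#' Linear elastic recoil above the unstressed volume, plus intrathoracic
#' pressure where applicable, plus the gravitational potential term
#' `g_level * posture_scale * height * density_factor`.  Because the height
#' is signed positive above heart level, the returned quantity is the
#' piezometric head whose differences drive inter-compartment flow; with
#' heart-level compartments at height 0 it coincides with their luminal
#' pressure.  Below the unstressed volume the elastic term is clamped at
#' zero: compartments do not generate suction.
#'
#' @param v compartment volume, mL (must be non-negative).
#' @param spec a compartment row (see [compartment_spec()]).
#' @param e_now instantaneous elastance, mmHg/mL; defaults to `spec$E` for
#'   vascular compartments and must be supplied (from
#'   [varying_elastance()]) for cardiac chambers.
#' @param globals a [global_params()] list.
#' @param posture_scale hydrostatic scale in `[0, 1]`; 1 standing, 0 supine.
#' @param vu_offset additive unstressed-volume offset, mL (protocol fluid
#'   shift and/or reflex venous tone).
#' @return pressure head, mmHg.
#' @export
compartment_pressure <- function(v, spec, e_now = NULL,
                                 globals = global_params(),
                                 posture_scale = 1, vu_offset = 0) {
  if (any(v < 0)) stop("negative compartment volume: integration failure")
  if (is.null(e_now)) {
    if (identical(spec$kind, "cardiac"))
      stop("cardiac compartments need e_now from varying_elastance()")
    e_now <- spec$E
  }
  elastic <- pmax(0, e_now * (v - (spec$vu + vu_offset)))
  elastic +
    (if (isTRUE(spec$thoracic)) globals$p_intrathoracic else 0) +
    globals$g_level * posture_scale * spec$height * globals$density_factor
}

#' Resistive flow across an edge
#'
#' Linear pressure-driven flow; valved edges are ideal diodes that pass no
#' backward flow.
#'
#' @param p_up,p_down upstream / downstream pressure head, mmHg.
#' @param r edge resistance, mmHg s/mL (> 0).
#' @param valved logical; one-way edge.
#' @return flow, mL/s.
#' @export
edge_flow <- function(p_up, p_down, r, valved = FALSE) {
  if (any(r <= 0)) stop("edge resistance must be positive")
  q <- (p_up - p_down) / r
  if (valved) q <- pmax(0, q)
  q
}

#' One-way lymphatic return flow
#'
#' @param p_tissue,p_svc pressure head of the drained compartment and of the
#'   superior vena cava, mmHg.
#' @param conductance mL/(s mmHg), >= 0.
#' @return flow, mL/s (never negative).
#' @export
lymphatic_flow <- function(p_tissue, p_svc, conductance) {
  if (any(conductance < 0)) stop("lymphatic conductance must be >= 0")
  pmax(0, conductance * (p_tissue - p_svc))
}

# smoothstep used by the venous-collapse outflow guard
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x^2 * (3 - 2 * x)
}

# outflow de-rating of a near-empty vascular compartment: full flow at or
# above 0.9 vu, zero at or below 0.8 vu.  Prevents gravity-driven siphoning
# of compartments below their unstressed volume (vessel collapse).
collapse_weight <- function(v, vu, cardiac) {
  ifelse(cardiac | vu <= 1, 1, smoothstep((v - 0.8 * vu) / (0.1 * vu)))
}

#' Volume derivatives of the full circuit
#'
#' Compartmental mass balance: for each compartment, the sum of inflows
#' minus outflows over the resistive and lymphatic edges.  This is the
#' reference R implementation of the right-hand side integrated (in
#' compiled code) by [simulate_model()]; the returned vector sums to zero
#' exactly because every edge moves volume between two compartments.
#'
#' @param volumes named (or ordered) vector of compartment volumes, mL.
#' @param model a `cp_model`.
#' @param phase cardiac phase in `[0, 1)`.
#' @param sf ventricular systolic fraction of the cycle.
#' @param sample protocol sample, a list with `g_level`, `posture_scale`,
#'   `shift` (see [sample_protocol()]).
#' @param mult reflex effector multipliers `c(hr, emax, r, vu)`.
#' @return named vector `dV/dt` (mL/s) with attributes `pressures`,
#'   `flows` and `lymph_flows`.
#' @export
circuit_derivatives <- function(volumes, model, phase = 0, sf = 0.33,
                                sample = list(g_level = 1, posture_scale = 0,
                                              shift = 0),
                                mult = c(1, 1, 1, 1)) {
  comp <- model$compartments
  if (any(!is.finite(volumes))) stop("non-finite volume: integration failure")
  gl <- model$globals
  gl$g_level <- sample$g_level
  n <- nrow(comp)
  p <- numeric(n)
  card <- comp$kind == "cardiac"
  for (i in seq_len(n)) {
    if (card[i]) {
      em <- comp$emax[i] * if (comp$emax_ctl[i]) mult[2] else 1
      e_now <- if (comp$atrial[i]) {
        varying_elastance((phase - .atrial_w0) %% 1, comp$emin[i], em,
                          1 - .atrial_w0)
      } else {
        varying_elastance(phase, comp$emin[i], em, sf)
      }
    } else e_now <- comp$E[i]
    dvu <- comp$dvu_0g[i] * sample$shift +
      if (comp$vu_ctl[i]) comp$vu[i] * (mult[4] - 1) else 0
    p[i] <- compartment_pressure(volumes[i], comp[i, ], e_now, gl,
                                 sample$posture_scale, dvu)
  }
  names(p) <- comp$name
  edges <- model$edges
  ifrom <- match(edges$from, comp$name)
  ito <- match(edges$to, comp$name)
  r_eff <- edges$R * ifelse(edges$r_ctl, mult[3], 1)
  q <- edge_flow(p[ifrom], p[ito], r_eff)
  q <- ifelse(edges$valved, pmax(0, q), q)
  w <- collapse_weight(volumes[ifrom], comp$vu[ifrom], card[ifrom])
  q <- ifelse(q > 0, q * w, q)
  dv <- numeric(n)
  for (j in seq_along(q)) {
    dv[ifrom[j]] <- dv[ifrom[j]] - q[j]
    dv[ito[j]] <- dv[ito[j]] + q[j]
  }
  ql <- numeric(0)
  if (nrow(model$lymph)) {
    lf <- match(model$lymph$from, comp$name)
    lt <- match(model$lymph$to, comp$name)
    ql <- lymphatic_flow(p[lf], p[lt], model$lymph$cond)
    ql <- ql * collapse_weight(volumes[lf], comp$vu[lf], card[lf])
    for (j in seq_along(ql)) {
      dv[lf[j]] <- dv[lf[j]] - ql[j]
      dv[lt[j]] <- dv[lt[j]] + ql[j]
    }
  }
  if (any(!is.finite(dv))) stop("non-finite flow: integration failure")
  structure(setNames(dv, comp$name), pressures = p, flows = q,
            lymph_flows = ql)
}
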