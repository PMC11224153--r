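#' Baroreflex configuration
#'
#' Set-point proportional controller with a first-order arterial pressure
#' sensor and four effectors, each with its own gain, time constant and
#' saturation bounds: heart rate (`hr`), ventricular contractility
#' (`emax`), arteriolar resistance (`r`) and venous unstressed volume
#' (`vu`).  A sensed pressure below the set point raises the heart-rate,
#' contractility and resistance multipliers and lowers the venous-tone
#' multiplier; at the set point every multiplier relaxes to 1.
#'
#' @param set_point target mean arterial pressure, mmHg.
#' @param sensor_tau time constant of the low-pass pressure sensor, s.
#' @param gains named vector of effector gains, 1/mmHg (magnitudes; the
#'   effector signs are fixed by physiology).
#' @param taus effector time constants, s.
#' @param lo,hi saturation bounds of the effector multipliers.
#' @return list of class `cp_reflex_config`.
#' @export
reflex_config <- function(set_point = 94, sensor_tau = 2,
                          gains = c(hr = 0.06, emax = 0.06, r = 0.05,
                                    vu = 0.04),
                          taus = c(hr = 3, emax = 8, r = 10, vu = 10),
                          lo = c(hr = 0.4, emax = 0.4, r = 0.4, vu = 0.6),
                          hi = c(hr = 2, emax = 2, r = 2.2, vu = 1.4)) {
  eff <- c("hr", "emax", "r", "vu")
  gains <- unlist(gains)[eff]; taus <- unlist(taus)[eff]
  lo <- unlist(lo)[eff]; hi <- unlist(hi)[eff]
  if (any(is.na(gains)) || any(gains < 0)) stop("need 4 non-negative gains")
  if (any(taus <= 0) || sensor_tau <= 0) stop("time constants must be > 0")
  if (set_point <= 0) stop("set point must be positive")
  if (any(lo >= 1) || any(hi <= 1) || any(lo <= 0))
    stop("saturation bounds must satisfy 0 < lo < 1 < hi")
  structure(list(set_point = set_point, sensor_tau = sensor_tau,
                 gains = gains, taus = taus, lo = lo, hi = hi),
            class = "cp_reflex_config")
}

#' Baroreflex state
#'
#' @param p_sensed low-pass filtered arterial pressure, mmHg.
#' @param mult effector multipliers `c(hr, emax, r, vu)`.
#' @return list of class `cp_reflex_state`.
#' @export
reflex_state <- function(p_sensed = 94, mult = c(hr = 1, emax = 1, r = 1,
                                                 vu = 1)) {
  stopifnot(is.finite(p_sensed))
  structure(list(p_sensed = p_sensed,
                 mult = setNames(as.numeric(mult),
                                 c("hr", "emax", "r", "vu"))),
            class = "cp_reflex_state")
}

#' One sensor update step
#'
#' First-order low-pass of the instantaneous arterial pressure:
#' `p_sensed <- p_sensed + dt/tau * (p_arterial - p_sensed)`.
#'
#' @param p_arterial instantaneous arterial pressure, mmHg.
#' @param state a [reflex_state()].
#' @param cfg a [reflex_config()].
#' @param dt step, s (> 0).
#' @return the updated state.
#' @export
reflex_sense <- function(p_arterial, state, cfg, dt) {
  stopifnot(dt > 0)
  state$p_sensed <- state$p_sensed +
    dt / cfg$sensor_tau * (p_arterial - state$p_sensed)
  state
}

#' One effector update step
#'
#' Each multiplier relaxes first-order toward a saturated linear function of
#' the pressure error `set_point - p_sensed`.
#'
#' @inheritParams reflex_sense
#' @return the updated state.
#' @export
reflex_effectors <- function(state, cfg, dt) {
  stopifnot(dt > 0)
  sign <- c(hr = 1, emax = 1, r = 1, vu = -1)
  err <- cfg$set_point - state$p_sensed
  target <- pmin(cfg$hi, pmax(cfg$lo, 1 + sign * cfg$gains * err))
  state$mult <- state$mult + dt / cfg$taus * (target - state$mult)
  state
}

#' Effective parameters under the current reflex state
#'
#' Returns the per-step effective heart rate, ventricular end-systolic
#' elastances, controlled edge resistances and controlled venous unstressed
#' volumes.  The base model is never mutated.
#'
#' @param model a `cp_model`.
#' @param state a [reflex_state()].
#' @return list with `hr`, `emax` (named, controlled chambers), `r` (named
#'   by `from->to`, controlled edges) and `vu` (named, controlled
#'   compartments).
#' @export
apply_effectors <- function(model, state) {
  m <- state$mult
  comp <- model$compartments
  ce <- comp$emax_ctl & comp$kind == "cardiac"
  cv <- comp$vu_ctl
  er <- model$edges$r_ctl
  list(hr = model$globals$hr0 * m[["hr"]],
       emax = setNames(comp$emax[ce] * m[["emax"]], comp$name[ce]),
       r = setNames(model$edges$R[er] * m[["r"]],
                    paste0(model$edges$from[er], "->", model$edges$to[er])),
       vu = setNames(comp$vu[cv] * m[["vu"]], comp$name[cv]))
}
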