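#' Define an experimental protocol
#'
#' A protocol is an ordered list of segments, each prescribing a gravity
#' level, a posture and a microgravity fluid-shift fraction, together with
#' the ramp duration over which the segment's values are reached by linear
#' interpolation from the previous segment.  Posture and gravity combine
#' into a single hydrostatic scale (standing at 1 G = 1, supine or 0 G =
#' 0); the shift fraction scales the per-compartment `dvu_0g`
#' unstressed-volume offsets of the model.
#'
#' @param segments data.frame with columns `t_start` (s), `g_level`,
#'   `posture` (`"standing"` or `"supine"`), `shift` (0..1) and `ramp` (s).
#' @param sample_times named numeric vector of labelled sampling times, s.
#' @param duration simulated horizon, s.
#' @return list of class `cp_protocol`.
#' @export
protocol <- function(segments, sample_times = c(pre = 80), duration = 90) {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "g_level", "posture", "shift", "ramp") %in%
                  names(segments)))
  if (is.unsorted(segments$t_start, strictly = TRUE))
    stop("segments must be strictly time-ordered")
  if (any(segments$ramp < 0)) stop("ramp durations must be >= 0")
  if (any(!segments$posture %in% c("standing", "supine")))
    stop("posture must be 'standing' or 'supine'")
  if (any(segments$g_level < 0)) stop("g_level must be >= 0")
  if (any(sample_times > duration))
    stop("sample times must lie within the simulated duration")
  segments$posture_scale <- ifelse(segments$posture == "standing", 1, 0)
  structure(list(segments = segments, sample_times = sample_times,
                 duration = duration),
            class = "cp_protocol")
}

#' Sample a protocol at a time point
#'
#' Piecewise-linear interpolation of the gravity level, posture scale and
#' fluid-shift fraction across each segment's entry ramp; constant within
#' segments; clamped to the final segment beyond the protocol horizon.
#'
#' @param prot a [protocol()].
#' @param t time, s (>= 0).
#' @param model optionally a `cp_model`; if given, the per-compartment
#'   unstressed-volume offsets `shift * dvu_0g` are included.
#' @return list with `g_level`, `posture_scale`, `shift` and (with a
#'   model) `vu_offset`.
#' @export
sample_protocol <- function(prot, t, model = NULL) {
  stopifnot(t >= 0)
  seg <- prot$segments
  k <- max(1, sum(seg$t_start <= t))
  g <- seg$g_level[k]; ps <- seg$posture_scale[k]; sh <- seg$shift[k]
  if (k > 1 && seg$ramp[k] > 0 && t < seg$t_start[k] + seg$ramp[k]) {
    f <- (t - seg$t_start[k]) / seg$ramp[k]
    g <- seg$g_level[k - 1] + f * (g - seg$g_level[k - 1])
    ps <- seg$posture_scale[k - 1] + f * (ps - seg$posture_scale[k - 1])
    sh <- seg$shift[k - 1] + f * (sh - seg$shift[k - 1])
  }
  out <- list(g_level = g, posture_scale = ps, shift = sh)
  if (!is.null(model))
    out$vu_offset <- setNames(model$compartments$dvu_0g * sh,
                              model$compartments$name)
  out
}

#' The standing-to-microgravity transition protocol
#'
#' 1 G in the chosen pre-transition posture until 125 s, a 10-s linear ramp
#' to 0 G (supine-equivalent, hydrostatic scale 0) with the full
#' microgravity fluid-shift unstressed-volume offsets, then steady 0 G.
#' Outputs are sampled at t = 80 s (`pre`) and t = 225 s (`post`).
#'
#' @param pre_posture posture held before the transition.
#' @return a [protocol()] of 250 s.
#' @export
microgravity_protocol <- function(pre_posture = c("standing", "supine")) {
  pre_posture <- match.arg(pre_posture)
  segs <- data.frame(
    t_start = c(0, 125),
    g_level = c(1, 0),
    posture = c(pre_posture, "supine"),
    shift = c(0, 1),
    ramp = c(0, 10))
  protocol(segs, sample_times = c(pre = 80, post = 225), duration = 250)
}

#' The supine 1-G baseline protocol
#'
#' A single steady segment: supine posture at Earth gravity, no fluid
#' shift, sampled at t = 80 s once the model has stabilized.
#'
#' @param duration simulated horizon, s.
#' @return a [protocol()].
#' @export
supine_baseline_protocol <- function(duration = 90) {
  segs <- data.frame(t_start = 0, g_level = 1, posture = "supine",
                     shift = 0, ramp = 0)
  protocol(segs, sample_times = c(pre = 80), duration = duration)
}

#' Deterministic toy circuits for unit testing
#'
#' Small 1-3 compartment fixtures with known closed-form behaviour:
#' \describe{
#'   \item{n = 1}{an elastic compartment draining through a resistance into
#'     a near-isobaric reservoir; the stressed volume decays exponentially
#'     with time constant R/E.}
#'   \item{n = 2}{two equal elastic compartments joined by one resistance;
#'     equal volumes are a symmetric equilibrium, unequal volumes relax
#'     toward it.}
#'   \item{n = 3}{a three-compartment ring with one valved edge; the
#'     equilibrium volumes follow from equal pressures and volume
#'     conservation, and flow through the valve is never negative.}
#' }
#' The seed perturbs elastances and resistances by up to +/-10% so that
#' parameterised tests do not rely on special symmetric values (n = 2 keeps
#' its symmetry); the same seed always yields the identical fixture.
#'
#' @param n number of elastic compartments, 1..3.
#' @param seed integer fixture seed.
#' @return list with `model`, `init` (initial volumes) and, where
#'   applicable, closed-form reference values (`tau`, `equilibrium`).
#' @export
toy_circuit <- function(n, seed = 1) {
  stopifnot(n %in% 1:3)
  jit <- function(k) {
    # deterministic jitter in [-0.1, 0.1] independent of the global RNG
    x <- sin(seed * 9301 + k * 49297) * 233280
    0.1 * (x - floor(x) - 0.5) * 2
  }
  gl <- global_params(total_blood_volume = 1, hr0 = 60)
  rf <- reflex_config(gains = c(hr = 0, emax = 0, r = 0, vu = 0))
  if (n == 1) {
    E <- 0.05 * (1 + jit(1)); R <- 1 * (1 + jit(2))
    comp <- rbind(
      compartment_spec("tank", "vascular", E = E, vu = 50),
      compartment_spec("reservoir", "vascular", E = 1e-6, vu = 0))
    edges <- data.frame(from = "tank", to = "reservoir", R = R,
                        valved = FALSE, r_ctl = FALSE)
    init <- c(tank = 50 + 40, reservoir = 1000)
    gl$total_blood_volume <- sum(init)
    model <- build_model(comp, edges, globals = gl, reflex = rf,
                         strict = FALSE)
    return(list(model = model, init = init, tau = R / E))
  }
  if (n == 2) {
    E <- 0.1 * (1 + jit(1)); R <- 0.5 * (1 + jit(2))
    comp <- rbind(
      compartment_spec("a", "vascular", E = E, vu = 20),
      compartment_spec("b", "vascular", E = E, vu = 20))
    edges <- data.frame(from = "a", to = "b", R = R,
                        valved = FALSE, r_ctl = FALSE)
    init <- c(a = 60, b = 60)
    gl$total_blood_volume <- sum(init)
    model <- build_model(comp, edges, globals = gl, reflex = rf,
                         strict = FALSE)
    return(list(model = model, init = init,
                equilibrium = c(a = 60, b = 60)))
  }
  E <- c(0.10, 0.05, 0.20) * (1 + vapply(1:3, jit, 0))
  R <- c(0.5, 0.8, 1.2) * (1 + vapply(4:6, jit, 0))
  vu <- c(10, 20, 5)
  comp <- do.call(rbind, lapply(1:3, function(i)
    compartment_spec(c("x", "y", "z")[i], "vascular", E = E[i],
                     vu = vu[i])))
  edges <- data.frame(from = c("x", "y", "z"), to = c("y", "z", "x"),
                      R = R, valved = c(TRUE, FALSE, FALSE),
                      r_ctl = FALSE)
  init <- c(x = 80, y = 30, z = 10)
  gl$total_blood_volume <- sum(init)
  model <- build_model(comp, edges, globals = gl, reflex = rf,
                       strict = FALSE)
  # equal-pressure equilibrium: V_i = vu_i + p/E_i,
  # p = (TBV - sum vu) / sum(1/E)
  p_eq <- (sum(init) - sum(vu)) / sum(1 / E)
  list(model = model, init = init,
       equilibrium = setNames(vu + p_eq / E, c("x", "y", "z")),
       p_eq = p_eq)
}
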