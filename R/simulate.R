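#' Integrate the circuit through a protocol
#'
#' Fixed-step explicit 4th-order (RK4) integration of the compartment
#' volumes, with a per-step baroreflex update and cardiac phase advance.
#' The phase increments by `dt * HR(t) / 60` and wraps at 1, emitting a
#' beat boundary; the ventricular systolic fraction is refreshed at each
#' beat from the current heart rate.  Total volume is conserved exactly by
#' construction (every flow moves volume between two compartments).
#'
#' The run is aborted with an error of class `gravicor_integration_failure`
#' (carrying the failure time) if any volume goes negative, any pressure
#' exceeds 500 mmHg in magnitude, or any state stops being finite.
#'
#' @param model a `cp_model`.
#' @param prot a [protocol()].
#' @param dt integration step, s (default 0.25 ms).
#' @param output_stride output sampling interval, s (default 5 ms).
#' @param duration simulated horizon, s; defaults to the protocol's.
#' @param open_loop freeze the baroreflex (all multipliers stay 1).
#' @param init_volumes optional initial volumes; defaults to
#'   [distribute_volumes()].
#' @return object of class `cp_sim`: sampled `time`, volume matrix `V`,
#'   pressure-head matrix `P`, edge flows `Q`, lymphatic flows `QL`,
#'   instantaneous heart rate `HR`, reflex multipliers `mult`, sensed
#'   pressure `p_sensed`, cardiac `phase`, beat boundary times `beats`,
#'   and the model/protocol used.
#' @export
simulate_model <- function(model, prot, dt = 2.5e-4, output_stride = 5e-3,
                           duration = NULL, open_loop = FALSE,
                           init_volumes = NULL) {
  stopifnot(inherits(model, "cp_model"), inherits(prot, "cp_protocol"),
            dt > 0)
  duration <- duration %||% prot$duration
  if (duration < max(c(0, prot$sample_times)))
    stop("duration must cover the protocol's sample times")
  stride <- max(1L, as.integer(round(output_stride / dt)))
  comp <- model$compartments
  card <- comp$kind == "cardiac"
  cpar <- cbind(ifelse(is.na(comp$E), 0, comp$E),
                ifelse(is.na(comp$emin), 0, comp$emin),
                ifelse(is.na(comp$emax), 0, comp$emax),
                comp$vu, comp$height, comp$dvu_0g,
                as.numeric(comp$thoracic), as.numeric(card),
                as.numeric(comp$atrial), as.numeric(comp$vu_ctl),
                as.numeric(comp$emax_ctl))
  epar <- cbind(match(model$edges$from, comp$name) - 1,
                match(model$edges$to, comp$name) - 1,
                model$edges$R, as.numeric(model$edges$valved),
                as.numeric(model$edges$r_ctl))
  if (nrow(model$lymph)) {
    lpar <- cbind(match(model$lymph$from, comp$name) - 1,
                  match(model$lymph$to, comp$name) - 1, model$lymph$cond)
  } else lpar <- matrix(numeric(0), 0, 3)
  seg <- prot$segments
  pm <- cbind(seg$t_start, seg$ramp, seg$g_level, seg$posture_scale,
              seg$shift)
  iao <- if ("ao_th" %in% comp$name) comp_index(model, "ao_th") else 1L
  glob <- c(model$globals$p_intrathoracic, model$globals$density_factor,
            model$globals$hr0, iao - 1)
  rf <- model$reflex
  rcfg <- c(rf$set_point, rf$sensor_tau,
            as.vector(rbind(rf$gains, rf$taus, rf$lo, rf$hi)))
  v0 <- init_volumes %||% distribute_volumes(model)
  if (!is.null(names(v0))) v0 <- v0[comp$name]
  v0 <- as.numeric(v0)
  if (length(v0) != nrow(comp) || any(!is.finite(v0)))
    stop("init_volumes must give one finite volume per compartment")

  res <- sim_core_cpp(cpar, epar, lpar, pm, glob, rcfg, v0, dt, duration,
                      stride, .atrial_w0, .sf_coef, open_loop)
  if (isTRUE(res$failed)) {
    cond <- structure(
      class = c("gravicor_integration_failure", "error", "condition"),
      list(message = sprintf(
        "integration failed at t = %.3f s (negative volume or |P| > 500 mmHg)",
        res$fail_time), call = sys.call(-1), time = res$fail_time))
    stop(cond)
  }
  k <- res$n_recorded
  en <- paste0(model$edges$from, "->", model$edges$to)
  out <- list(
    time = res$time[seq_len(k)],
    V = `colnames<-`(res$V[seq_len(k), , drop = FALSE], comp$name),
    P = `colnames<-`(res$P[seq_len(k), , drop = FALSE], comp$name),
    Q = `colnames<-`(res$Q[seq_len(k), , drop = FALSE], en),
    QL = if (nrow(model$lymph))
      `colnames<-`(res$QL[seq_len(k), , drop = FALSE],
                   paste0(model$lymph$from, "->", model$lymph$to))
    else res$QL[seq_len(k), , drop = FALSE],
    HR = res$HR[seq_len(k)],
    mult = `colnames<-`(res$mult[seq_len(k), , drop = FALSE],
                        c("hr", "emax", "r", "vu")),
    p_sensed = res$p_sensed[seq_len(k)],
    phase = res$phase[seq_len(k)],
    sf = res$sf[seq_len(k)],
    beats = res$beats,
    dt = dt, output_stride = stride * dt,
    model = model, protocol = prot)
  class(out) <- "cp_sim"
  out
}

#' @export
print.cp_sim <- function(x, ...) {
  cat("<cp_sim> ", length(x$time), " samples over ",
      round(max(x$time), 2), " s, ", length(x$beats), " beats, dt = ",
      x$dt * 1000, " ms\n", sep = "")
  invisible(x)
}

#' Check beat-to-beat stationarity before a sample time
#'
#' Verifies that the beat-averaged metrics of the `n_beats` complete beats
#' preceding `sample_t` vary by less than `tol` (relative), i.e. that the
#' model has stabilized before the protocol's sampling point.
#'
#' @param sim a `cp_sim`.
#' @param sample_t sampling time, s.
#' @param n_beats number of trailing beats to compare.
#' @param tol maximum allowed relative beat-to-beat variation.
#' @return logical; attribute `max_rel` carries the worst relative
#'   variation observed.
#' @export
is_stationary <- function(sim, sample_t, n_beats = 5, tol = 0.01) {
  b <- sim$beats[sim$beats <= sample_t]
  if (length(b) < n_beats + 1) stop("not enough complete beats before t = ",
                                    sample_t)
  ms <- lapply(seq_len(n_beats), function(i) {
    bm <- beat_metrics(sim, b[length(b) - i + 1])
    unlist(bm[c("co", "hr", "map", "lvedv")])
  })
  m <- do.call(rbind, ms)
  rel <- apply(m, 2, function(v) (max(v) - min(v)) / max(abs(mean(v)), 1e-9))
  structure(all(rel < tol), max_rel = max(rel))
}
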