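# Base-graphics views of PV loops and transition dynamics.

#' @export
plot.cp_pv_loop <- function(x, ..., col = "steelblue", add = FALSE) {
  if (!add)
    graphics::plot(x$v, x$p, type = "l", col = col,
                   xlab = "LV volume (mL)", ylab = "LV pressure (mmHg)",
                   main = paste("PV loop -", attr(x, "scenario")), ...)
  else graphics::lines(x$v, x$p, col = col, ...)
  invisible(x)
}

#' Plot the hemodynamic transition response
#'
#' MAP, heart rate, cardiac-output proxy and LAP against time, with the
#' transition onset marked; one panel layout per simulation.
#'
#' @param sim a `cp_sim` run under a transition protocol.
#' @param t_on transition onset time to mark, s.
#' @export
plot_transition <- function(sim, t_on = 125) {
  op <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  t <- sim$time
  graphics::plot(t, sim$P[, "ao_th"], type = "l", col = "red",
                 xlab = "time (s)", ylab = "pressure (mmHg)",
                 ylim = c(0, max(sim$P[, "ao_th"])))
  graphics::lines(t, sim$P[, "la"], col = "blue")
  graphics::abline(v = t_on, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(t, sim$HR, type = "l", col = "darkgreen", lty = 3,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("HR (bpm)", side = 4, line = 2.5)
  graphics::legend("topright", c("MAP", "LAP", "HR"),
                   col = c("red", "blue", "darkgreen"),
                   lty = c(1, 1, 3), bty = "n")
  invisible(sim)
}
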