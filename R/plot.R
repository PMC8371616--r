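#' Plot a simulated waveform
#'
#' Three stacked panels in the style of a ventilator monitor: flow (L/min),
#' pressures (airway, alveolar and muscle, cmH2O) and volume above FRC (mL).
#' Breath starts are marked with dotted vertical lines.
#'
#' @param x a `vent_waveform`.
#' @param window optional `c(from, to)` time window in seconds.
#' @param ... unused.
#' @export
plot.vent_waveform <- function(x, window = NULL, ...) {
  d <- x$data
  if (!is.null(window)) d <- d[d$t >= window[1] & d$t <= window[2], ]
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1), oma = c(2, 0, 2, 0))
  on.exit(graphics::par(op), add = TRUE)
  starts <- x$breaths$t_start
  if (!is.null(window)) starts <- starts[starts >= window[1] & starts <= window[2]]

  graphics::plot(d$t, d$flow_lpm, type = "l", col = "blue",
                 xlab = "", ylab = "flow (L/min)")
  graphics::abline(h = 0, col = "grey70"); graphics::abline(v = starts, lty = 3, col = "grey50")
  graphics::plot(d$t, d$p_aw, type = "l", col = "red", ylim = range(c(d$p_aw, d$p_alv, d$p_mus)),
                 xlab = "", ylab = "pressure (cmH2O)")
  graphics::lines(d$t, d$p_alv, col = "darkgreen")
  graphics::lines(d$t, d$p_mus, col = "purple")
  graphics::legend("topright", c("airway", "alveolar", "muscle"),
                   col = c("red", "darkgreen", "purple"), lty = 1, cex = 0.7, bty = "n")
  graphics::abline(v = starts, lty = 3, col = "grey50")
  graphics::plot(d$t, d$volume_ml, type = "l", col = "grey30",
                 xlab = "time (s)", ylab = "volume (mL)")
  graphics::abline(v = starts, lty = 3, col = "grey50")
  graphics::mtext(x$scenario$label, outer = TRUE, line = 0.5)
  invisible(x)
}
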