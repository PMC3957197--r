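# Base-graphics plot methods for the container classes.

#' @export
plot.track <- function(x, ...) {
  R <- x$header$arena_diameter_cm / 2
  a <- seq(0, 2 * pi, length.out = 361)
  plot(R * cos(a), R * sin(a), type = "l", asp = 1, xlab = "x (cm)",
       ylab = "y (cm)", main = sprintf("%s %s s%d", x$header$rat_id,
                                       x$header$phase_label,
                                       x$header$session_index), ...)
  lines(x$data$x_cm, x$data$y_cm, col = "grey30")
  sh <- x$data$shock_flag == 1
  if (any(sh)) points(x$data$x_cm[sh], x$data$y_cm[sh], col = "red",
                      pch = 4)
  half <- x$header$sector_width_deg / 2 * pi / 180
  ctr <- x$header$sector_center_deg * pi / 180
  for (b in c(ctr - half, ctr + half))
    lines(c(0, R * cos(b)), c(0, R * sin(b)), lty = 2, col = "red")
  invisible(x)
}

#' @export
plot.actogram <- function(x, ...) {
  m <- x$mat
  m[is.na(m)] <- 0
  graphics::image(
    x = seq(0, 48, length.out = ncol(m) + 1),
    y = seq_len(nrow(m) + 1) - 0.5,
    z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
    col = grDevices::grey(seq(1, 0, length.out = 64)),
    xlab = "time (h, double-plotted)", ylab = "day", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(seq_len(nrow(m))))
  graphics::abline(v = 24, col = "red", lty = 3)
  invisible(x)
}

#' @export
plot.periodogram <- function(x, ...) {
  plot(x$table$period_h, x$table$Q, type = "l", xlab = "period (h)",
       ylab = expression(Q[P]), main = x$method, ...)
  lines(x$table$period_h, x$table$sig_line, lty = 2, col = "red")
  if (!is.na(x$tau_hat))
    graphics::abline(v = x$tau_hat, col = "blue", lty = 3)
  invisible(x)
}
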