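# Base-graphics visualization helpers (static exports).

#' Plot the cell configuration of a state
#'
#' Filled image of the summed cell indicators with 0.5-level contours per
#' cell and the epithelial boundary.
#'
#' @param x a [pf_state()].
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @export
plot.pf_state <- function(x, main = sprintf("t = %g", x$time), ...) {
  g <- x$grid
  total <- apply(x$phi, c(1, 2), sum)
  graphics::image(g$x, g$y, total, col = grDevices::hcl.colors(32, "YlOrBr",
                                                               rev = TRUE),
                  xlab = "x (anterior - posterior)", ylab = "y", main = main,
                  asp = 1, ...)
  for (m in seq_len(dim(x$phi)[3]))
    graphics::contour(g$x, g$y, x$phi[, , m], levels = 0.5, add = TRUE,
                      drawlabels = FALSE,
                      col = if (m == x$cluster) "darkgreen"
                            else if (!is.na(x$oocyte) && m == x$oocyte) "blue"
                            else "red")
  graphics::contour(g$x, g$y, x$phi0, levels = 0.5, add = TRUE,
                    drawlabels = FALSE, col = "black", lwd = 2)
  invisible(x)
}

#' Plot a scenario run: centroid path and A-P position over time
#'
#' @param x a `pf_run`.
#' @param ... unused.
#' @export
plot.pf_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot.pf_state(x$state, main = sprintf("%s (t = %g)", x$scenario, x$state$time))
  graphics::lines(x$traj$x_c, x$traj$y_c, lwd = 2, col = "purple")
  graphics::plot(x$traj$t, x$traj$x_c, type = "l", lwd = 2,
                 xlab = "t", ylab = "cluster x position", main = "A-P progress")
  invisible(x)
}
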