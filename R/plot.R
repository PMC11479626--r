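# Base-graphics display helpers.

#' Display an image matrix with physical axes
#'
#' @param x image matrix (rows = x)
#' @param dx,dy pixel pitches in nm
#' @param main title
#' @param ... passed to [graphics::image()]
#' @return invisibly, `x`
#' @export
plot_image <- function(x, dx = 1, dy = dx, main = NULL, ...) {
  graphics::image(x = (seq_len(nrow(x)) - 1) * dx / 1000,
                  y = (seq_len(ncol(x)) - 1) * dy / 1000,
                  z = x, col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (um)", ylab = "y (um)", main = main,
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' @export
plot.rim_fit <- function(x, which = c("rho", "objective"), ...) {
  which <- match.arg(which)
  if (which == "rho") plot_image(x$rho, main = "reconstructed density", ...)
  else {
    graphics::plot(seq_along(x$objective) - 1, x$objective, type = "b",
                   log = "y", xlab = "iteration", ylab = "objective", ...)
  }
  invisible(x)
}

#' @export
plot.resolution_report <- function(x, ...) {
  p <- x$modulation_profile
  graphics::plot(p$radius_nm, p$contrast, type = "l",
                 xlab = "radius (nm)", ylab = "modulation contrast", ...)
  graphics::abline(h = x$contrast_criterion, lty = 2)
  if (!is.na(x$min_resolved_radius))
    graphics::abline(v = x$min_resolved_radius, lty = 3)
  invisible(x)
}

#' @export
plot.surface_estimate <- function(x, ...) {
  plot_image(x$z_grid, x$grid$dx, x$grid$dy, main = "estimated surface (nm)", ...)
  invisible(x)
}
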