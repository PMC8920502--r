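#' Plot a reactive-trajectory density map
#'
#' Filled contour of the smoothed density with optional shortest-path
#' overlay.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param main plot title.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plotDensityMap <- function(map, main = "Reactive trajectory density", ...) {
  nb <- nrow(map@values)
  x <- seq(map@bounds[1L, 1L], map@bounds[2L, 1L], length.out = nb)
  y <- seq(map@bounds[1L, 2L], map@bounds[2L, 2L], length.out = nb)
  graphics::image(x, y, map@values,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = paste("feature", map@axes[1L]),
                  ylab = paste("feature", map@axes[2L]), main = main, ...)
  graphics::contour(x, y, map@values, add = TRUE, drawlabels = FALSE,
                    col = "grey40", nlevels = 8)
}

#' Plot a quasi-potential profile
#'
#' @param qp a \linkS4class{QuasiPotential}.
#' @param add overlay on an existing plot.
#' @param ... passed to \code{\link[graphics]{plot}} / \code{lines}.
#' @export
plotQuasiPotential <- function(qp, add = FALSE, ...) {
  if (add) graphics::lines(qp@sGrid, qp@phi, ...)
  else graphics::plot(qp@sGrid, qp@phi, type = "l", xlab = "s",
                      ylab = expression(phi(s)), ...)
  if (any(qp@masked))
    graphics::points(qp@sGrid[qp@masked], qp@phi[qp@masked], pch = 1,
                     col = "grey50")
}

#' Overlay reaction coordinates on trajectory data
#'
#' Scatter of all ensemble frames in a feature plane with the RC image
#' chains drawn on top.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param rcs list of \linkS4class{ReactionCoordinate}s.
#' @param axes the two feature indices to plot.
#' @export
plotRCOverlay <- function(ensemble, rcs, axes = c(1L, 2L)) {
  pts <- ensemblePoints(ensemble)$points[, axes, drop = FALSE]
  graphics::plot(pts, pch = ".", col = "grey70",
                 xlab = paste("feature", axes[1L]),
                 ylab = paste("feature", axes[2L]))
  cols <- c("firebrick", "navy", "darkgreen", "orange")
  for (g in seq_along(rcs)) {
    img <- images(rcs[[g]])[, axes, drop = FALSE]
    graphics::lines(img, col = cols[(g - 1L) %% 4L + 1L], lwd = 2)
    graphics::points(img, col = cols[(g - 1L) %% 4L + 1L], pch = 19,
                     cex = 0.6)
  }
}
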