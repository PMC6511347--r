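# Radar dot-plot rendering with gate overlays (base graphics).

#' Plot a radar dot-plot with gate overlays
#'
#' Draws projected events as a dot-plot with the tube's template gates
#' overlaid (bold outline: hypergranular gate; grey outline: microgranular
#' gate), the visual used to read a case at a glance.
#'
#' @param points n x 2 matrix of projected coordinates.
#' @param gates list of `gate_region` objects to overlay.
#' @param main plot title.
#' @param col point color.
#' @param max_points subsample cap for rendering speed.
#' @return invisibly, NULL.
#' @export
plot_radar <- function(points, gates = list(), main = "radar dot-plot",
                       col = grDevices::rgb(0.8, 0, 0, 0.15),
                       max_points = 20000) {
  points <- as.matrix(points)
  if (nrow(points) > max_points)
    points <- points[seq(1, nrow(points), length.out = max_points), ]
  lim <- range(c(points,
                 unlist(lapply(gates, function(g) g$vertices))))
  graphics::plot(points[, 1], points[, 2], pch = ".", col = col,
                 xlim = lim, ylim = lim, asp = 1,
                 xlab = "radar x", ylab = "radar y", main = main)
  for (g in gates) {
    v <- rbind(g$vertices, g$vertices[1, ])
    graphics::lines(v[, 1], v[, 2],
                    lwd = if (g$type == "hypergranular") 2.5 else 1.5,
                    col = if (g$type == "hypergranular") "black" else "grey50")
  }
  invisible(NULL)
}
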