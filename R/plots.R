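#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulated release curves
#'
#' @param object A `ca_result`.
#' @param ... Unused.
#' @return A ggplot of cumulative release per species vs time.
#' @method autoplot ca_result
#' @export
autoplot.ca_result <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$time_s, y = .data$released_pct,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Released (% of dose)",
                  colour = "Species") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a Noyes-Whitney fit
#'
#' @param object An `nw_fit`.
#' @param ... Unused.
#' @return A ggplot of observed points and the fitted first-order curve.
#' @method autoplot nw_fit
#' @export
autoplot.nw_fit <- function(object, ...) {
  r <- object$residuals
  tt <- seq(min(r$time_s), max(r$time_s), length.out = 200)
  s <- object$settings
  curve <- tibble::tibble(
    time_s = tt,
    released_pct = s$Cs * (1 - exp(-(s$D * object$S_hat / s$h) * tt))
  )
  ggplot2::ggplot(r, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$released_pct),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "Time (s)", y = "Released (% of dose)",
      title = sprintf("S = %.3g cm^2/g, R^2 = %.4f",
                      object$S_hat, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a horizontal slice of a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @param z Slice index along the compression axis (default: mid-height).
#' @return A ggplot raster of voxel states (liquid, pore, one tile per
#'   species).
#' @export
plot_grid_slice <- function(grid, z = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$state)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- grid$state[, , z]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$state <- as.vector(sl)
  lab <- c("liquid", "pore", grid$species$name)
  code <- c(VX_LIQUID, VX_PORE, grid$species$species_id)
  df$what <- factor(lab[match(df$state, code)], levels = unique(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$what)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = NULL, title = sprintf("z = %d", z)) +
    ggplot2::theme_void()
}
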