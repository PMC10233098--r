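# Plot helpers (ggplot2, suggested dependency). Each returns a ggplot
# object built from the run's own data; nothing is written to disk here.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_kinvae("ggplot2 is required for plotting", "kinvae_plot_error")
  }
}

#' Scatter plot of latent points by group
#'
#' @param projection A `kinvae_projection` from [project_latent()].
#' @param level `"participant"` (default) or `"task"`.
#' @param dims Two latent dimensions to display (default 1:2).
#' @return A ggplot object.
#' @export
plot_latent <- function(projection, level = c("participant", "task"),
                        dims = c(1, 2)) {
  need_ggplot()
  level <- match.arg(level)
  pts <- if (level == "participant") projection$participant_points else
    projection$task_points
  zx <- paste0("z", dims[1]); zy <- paste0("z", dims[2])
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data[[zx]], y = .data[[zy]],
    colour = factor(.data$group, levels = 0:1, labels = c("TD", "ASD")))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(TD = "#d62728", ASD = "#1f77b4"),
                                 name = NULL) +
    ggplot2::labs(x = zx, y = zy) +
    ggplot2::theme_minimal()
}

#' Plot a feature's assignment-probability response curve
#'
#' @param curve A `kinvae_curve` from [feature_response_curve()].
#' @return A ggplot object with the TD and ASD posterior curves and their
#'   across-participant SD ribbons.
#' @export
plot_response_curve <- function(curve) {
  need_ggplot()
  df <- rbind(
    data.frame(value = curve$value, p = curve$p_td, sd = curve$sd_td,
               class = "TD"),
    data.frame(value = curve$value, p = curve$p_asd, sd = curve$sd_asd,
               class = "ASD")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$p,
                                   colour = .data$class,
                                   fill = .data$class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$p - .data$sd, 0),
                                      ymax = pmin(.data$p + .data$sd, 1)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(TD = "#d62728", ASD = "#1f77b4"),
                                 name = NULL,
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = curve$feature[1], y = "assignment probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation density map in the latent plane
#'
#' @param density A `kinvae_density` from [feature_density_map()].
#' @param projection Optional `kinvae_projection` whose participant points
#'   are overlaid for orientation.
#' @return A ggplot object.
#' @export
plot_density_map <- function(density, projection = NULL) {
  need_ggplot()
  grid <- expand.grid(x = density$x, y = density$y)
  grid$d <- as.vector(density$density)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$d)) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 name = "density") +
    ggplot2::labs(x = "z1", y = "z2", title = density$feature_name) +
    ggplot2::theme_minimal()
  if (!is.null(projection)) {
    pts <- projection$participant_points
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$z1, y = .data$z2,
                   colour = factor(.data$group, levels = 0:1,
                                   labels = c("TD", "ASD"))),
      inherit.aes = FALSE, size = 1) +
      ggplot2::scale_colour_manual(
        values = c(TD = "#d62728", ASD = "#1f77b4"), name = NULL)
  }
  p
}
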