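# ggplot2 views of summaries and digitized specimens.

#' Plot an architecture summary
#'
#' Median with min-max range per tear category, faceted by region and part.
#'
#' @param object A [summarize_architecture()] result.
#' @param metric Metric to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fascicle_summary <- function(object,
                                      metric = c("fbl_cm", "lat_pa_deg", "med_pa_deg"),
                                      ...) {
  metric <- match.arg(metric)
  lab <- c(
    fbl_cm = "Fiber bundle length (cm)",
    lat_pa_deg = "Lateral pennation angle (deg)",
    med_pa_deg = "Medial pennation angle (deg)"
  )[[metric]]
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$category,
      y = .data[[paste0(metric, "_median")]],
      ymin = .data[[paste0(metric, "_min")]],
      ymax = .data[[paste0(metric, "_max")]],
      color = .data$part
    )
  ) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "Tear category", y = lab, color = "Part") +
    ggplot2::theme_minimal()
}

#' Plot a digitized specimen in a projection plane
#'
#' Fiber bundles as paths colored by part, the tendon axis emphasized, in a
#' 2D orthographic projection of the digitized coordinates.
#'
#' @param points Long point table of one specimen.
#' @param plane `"xy"` (superior view, default) or `"xz"` (depth view).
#' @return A ggplot.
#' @export
plot_specimen <- function(points, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  yvar <- if (plane == "xy") "y_cm" else "z_cm"
  fibers <- dplyr::filter(points, .data$record_type == "fiber")
  axis_pts <- dplyr::filter(points, .data$record_type == "tendon_axis")
  ggplot2::ggplot(fibers, ggplot2::aes(x = .data$x_cm, y = .data[[yvar]])) +
    ggplot2::geom_path(
      ggplot2::aes(group = .data$record_id, color = .data$part),
      alpha = 0.5, linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = axis_pts,
      ggplot2::aes(group = .data$record_id),
      color = "black", linewidth = 1
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Medial-lateral (cm)",
      y = if (plane == "xy") "Posterior-anterior (cm)" else "Depth (cm)",
      color = "Part"
    ) +
    ggplot2::theme_minimal()
}
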