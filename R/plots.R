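# Figure helpers (ggplot2, suggested dependency).

#' Per-segment distance bars with IQR
#'
#' Median distance between individual and reference contours per wall and
#' level, faceted by view and phase.
#'
#' @param summary output of [aggregate_distance_summary()].
#' @return A ggplot object.
#' @export
plot_segment_distances <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_segment_distances requires the ggplot2 package", call. = FALSE)
  }
  s <- summary[summary$grouping == "segment", ]
  ggplot2::ggplot(s, ggplot2::aes(x = region, y = median_mm)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = q25_mm, ymax = q75_mm),
                           width = 0.3) +
    ggplot2::facet_grid(phase ~ view) +
    ggplot2::labs(x = NULL, y = "distance to reference contour [mm]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Landmark scatter with concentric 1/4/9 cm^2 rings
#'
#' Offsets of each observer's annulus/apex positions from the cohort
#' reference position, with the three concentric area circles overlaid.
#'
#' @param offsets output of [compute_landmark_offsets()].
#' @return A ggplot object.
#' @export
plot_landmark_scatter <- function(offsets) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_landmark_scatter requires the ggplot2 package", call. = FALSE)
  }
  th <- seq(0, 2 * pi, length.out = 181L)
  rings <- do.call(rbind, lapply(area_bin_radii(), function(r)
    data.frame(x = r * cos(th), y = r * sin(th), r = r)))
  offsets$panel <- paste(offsets$view, offsets$phase)
  ggplot2::ggplot(offsets, ggplot2::aes(x = dx, y = dy)) +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(x = x, y = y, group = r),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::facet_grid(panel ~ kind) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "offset x [mm]", y = "offset y [mm]") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("region", "median_mm", "q25_mm", "q75_mm",
                         "dx", "dy", "x", "y", "r", "panel", "kind"))
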