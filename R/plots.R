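#' Plot a tracked centerline
#'
#' Sagittal-plane (x-z) projection of the centerline, coloured by the plane
#' kind each point was tracked on, with point size following the local
#' diameter.
#'
#' @param object A `tac_centerline` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tac_centerline
#' @export
autoplot.tac_centerline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$z,
                                       colour = .data$plane,
                                       size = .data$diameter_mm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.3, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", colour = "plane",
                  size = "diameter (mm)",
                  title = "Aortic centerline (sagittal projection)") +
    ggplot2::theme_minimal()
}

#' Plot the diameter profile along the vessel
#'
#' @param centerline A `tac_centerline` tibble.
#' @param segments Optional `tac_segments` tibble; segment boundaries are
#'   drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_diameter_profile <- function(centerline, segments = NULL) {
  p <- ggplot2::ggplot(centerline,
                       ggplot2::aes(x = .data$arc_mm, y = .data$diameter_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (mm)", y = "diameter (mm)",
                  title = "Lumen diameter along the thoracic aorta") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_vline(xintercept = segments$end_mm[-5],
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot per-segment TAC prevalence
#'
#' @param data A subject tibble (prevalence is computed with
#'   [prevalence_by_segment()]) or a precomputed prevalence tibble.
#' @return A ggplot bar chart of the proportion of subjects with a positive
#'   score in each segment.
#' @export
plot_segment_prevalence <- function(data) {
  prev <- if (all(c("segment", "pct") %in% names(data))) data else {
    prevalence_by_segment(data)
  }
  ggplot2::ggplot(prev, ggplot2::aes(x = factor(.data$segment), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "aortic segment", y = "subjects with TAC > 0 (%)",
                  title = "TAC prevalence by aortic segment") +
    ggplot2::theme_minimal()
}

#' Plot the spatial lesion distribution
#'
#' @param dist A tibble from [lesion_distribution()].
#' @return A ggplot object: lesion counts per segment, annotated with the
#'   share of the total, and lesions per cm when available.
#' @export
plot_lesion_distribution <- function(dist) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$segment),
                                          y = .data$n_lesions)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$share_pct, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "aortic segment", y = "number of calcifications",
                  title = "Spatial distribution of calcifications") +
    ggplot2::theme_minimal()
  p
}

#' Plot TAC prevalence by age tertile
#'
#' @param tert A tibble from [age_tertile_prevalence()].
#' @return A ggplot object: grouped bars of per-segment (and any-segment)
#'   prevalence, one colour per age tertile.
#' @export
plot_age_tertile_prevalence <- function(tert) {
  tert$measure <- factor(tert$measure,
                         levels = c(paste0("seg", 1:5), "any"))
  ggplot2::ggplot(tert, ggplot2::aes(x = .data$measure, y = .data$pct,
                                     fill = factor(.data$tertile))) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "subjects with TAC > 0 (%)",
                  fill = "age tertile",
                  title = "TAC prevalence by age tertile") +
    ggplot2::theme_minimal()
}
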