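ellipse_path <- function(center, l1, l2, major_dir, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- l1 / 2; b <- l2 / 2
  u <- center[1] + a * cos(t) * major_dir[1] - b * sin(t) * major_dir[2]
  v <- center[2] + a * cos(t) * major_dir[2] + b * sin(t) * major_dir[1]
  tibble::tibble(u = u, v = v)
}

circle_path <- function(center, radius, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(u = center[1] + radius * cos(t),
                 v = center[2] + radius * sin(t))
}

#' Plot a contour parametrisation
#'
#' Shows the two projection stages side by side: the cloud projected onto
#' its least-squares plane with the fitted ellipse, and the cloud projected
#' along the ellipse minor axis with the fitted circle (the curvature view).
#'
#' @param object A [parametrise_contour()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contour_parameters
#' @export
autoplot.contour_parameters <- function(object, ...) {
  efit <- object$proj$ellipse
  pts <- dplyr::bind_rows(
    dplyr::mutate(object$proj$ellipse_points, stage = "ellipse plane"),
    dplyr::mutate(object$proj$circle_points, stage = "curvature view")
  )
  curves <- dplyr::mutate(
    ellipse_path(efit$center, efit$l1, efit$l2, efit$major_dir),
    stage = "ellipse plane"
  )
  if (!object$circle_degenerate) {
    cfit <- object$proj$circle
    curves <- dplyr::bind_rows(
      curves,
      dplyr::mutate(circle_path(cfit$center, cfit$radius),
                    stage = "curvature view")
    )
  }
  pts$stage <- factor(pts$stage, levels = c("ellipse plane", "curvature view"))
  curves$stage <- factor(curves$stage, levels = levels(pts$stage))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_path(data = curves, colour = "#D55E00") +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u (mm)", y = "v (mm)",
      title = sprintf("L1 = %.1f mm, L2 = %.1f mm, r = %s mm",
                      object$l1, object$l2,
                      if (is.finite(object$r)) sprintf("%.1f", object$r)
                      else "Inf (flat)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reliability report
#'
#' Dot plot of the intra- and inter-observer ICC per parameter and cartilage
#' type, with the qualitative classification bands (0.5, 0.75, 0.90) drawn
#' as reference lines.
#'
#' @param object A [reliability_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reliability_report
#' @export
autoplot.reliability_report <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::all_of(c("cartilage_type", "parameter",
                                  "icc_intra", "icc_inter"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("icc_intra", "icc_inter")),
                        names_to = "condition", values_to = "icc") |>
    dplyr::mutate(condition = ifelse(.data$condition == "icc_intra",
                                     "intra-observer", "inter-observer"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$icc, y = .data$parameter,
                                     colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~cartilage_type) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "ICC", y = NULL, colour = NULL,
                  title = "Relative reliability by parameter") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reliability_report
#' @param report A [reliability_report()] tibble.
#' @export
plot_reliability <- function(report, ...) {
  autoplot.reliability_report(report, ...)
}
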