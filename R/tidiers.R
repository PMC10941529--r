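#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a plane fit
#'
#' @param x A [fit_plane()] result.
#' @param ... Unused.
#' @return One-row tibble with the centroid, normal components and rms
#'   orthogonal distance.
#' @method tidy plane_fit
#' @export
tidy.plane_fit <- function(x, ...) {
  tibble::tibble(
    centroid_x = x$centroid[1], centroid_y = x$centroid[2],
    centroid_z = x$centroid[3],
    normal_x = x$normal[1], normal_y = x$normal[2], normal_z = x$normal[3],
    rms_distance = x$rms_distance, n = x$n
  )
}

#' @rdname tidy.plane_fit
#' @method glance plane_fit
#' @export
glance.plane_fit <- function(x, ...) {
  tibble::tibble(rms_distance = x$rms_distance, n = x$n)
}

#' Tidy an ellipse fit
#'
#' @param x A [fit_ellipse()] result.
#' @param ... Unused.
#' @return One-row tibble with centre, axis lengths, major-axis direction
#'   and residual.
#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    center_u = x$center[1], center_v = x$center[2],
    l1 = x$l1, l2 = x$l2,
    major_u = x$major_dir[1], major_v = x$major_dir[2],
    rms = x$rms_orthogonal_residual, n = x$n
  )
}

#' @rdname tidy.ellipse_fit
#' @method glance ellipse_fit
#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, rms = x$rms_orthogonal_residual,
                 converged = x$converged, n = x$n)
}

#' Tidy a circle fit
#'
#' @param x A [fit_circle()] result.
#' @param ... Unused.
#' @return One-row tibble with centre, radius and residual.
#' @method tidy circle_fit
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(center_u = x$center[1], center_v = x$center[2],
                 radius = x$radius, rms = x$rms_residual, n = x$n)
}

#' @rdname tidy.circle_fit
#' @method glance circle_fit
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, rms = x$rms_residual, n = x$n)
}

#' Tidy a contour parametrisation
#'
#' @param x A [parametrise_contour()] result.
#' @param ... Unused.
#' @return One-row tibble with the nine parameters (`x, y, z` mm,
#'   `alpha, beta, gamma` deg, `l1, l2, r` mm), the three fit residuals and
#'   the quality flags.
#' @method tidy contour_parameters
#' @export
tidy.contour_parameters <- function(x, ...) {
  obj <- x
  tibble::tibble(
    x = obj$position[["x"]], y = obj$position[["y"]], z = obj$position[["z"]],
    alpha = obj$angles[["alpha"]], beta = obj$angles[["beta"]],
    gamma = obj$angles[["gamma"]],
    l1 = obj$l1, l2 = obj$l2, r = obj$r,
    plane_rms = obj$residuals[["plane"]],
    ellipse_rms = obj$residuals[["ellipse"]],
    circle_rms = obj$residuals[["circle"]],
    circle_degenerate = obj$circle_degenerate,
    flat = obj$flat, n = obj$n
  )
}

#' @rdname tidy.contour_parameters
#' @method glance contour_parameters
#' @export
glance.contour_parameters <- function(x, ...) {
  tibble::tibble(
    plane_rms = x$residuals[["plane"]],
    ellipse_rms = x$residuals[["ellipse"]],
    circle_rms = x$residuals[["circle"]],
    circle_degenerate = x$circle_degenerate,
    gimbal_lock = x$gimbal_lock, n = x$n
  )
}

#' Tidy variance components
#'
#' @param x An [estimate_variance_components()] result.
#' @param ... Unused.
#' @return Long tibble: one row per component with its truncated and raw
#'   estimates.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  comp <- c("cartilage", "operator", "digitalisation", "residual")
  tibble::tibble(
    component = comp,
    sigma2 = c(x$sigma2_cartilage, x$sigma2_operator,
               x$sigma2_digitalisation, x$sigma2_residual),
    sigma2_raw = unname(x$raw[comp])
  )
}

#' @rdname tidy.variance_components
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(sigma2_total = x$sigma2_total, method = x$method, n = x$n)
}

#' Tidy a pivot calibration
#'
#' @param x A [pivot_calibrate()] result.
#' @param ... Unused.
#' @return One-row tibble with the tip offset, pivot point and rms scatter.
#' @method tidy pivot_calibration
#' @export
tidy.pivot_calibration <- function(x, ...) {
  tibble::tibble(
    tip_x = x$tip_offset[1], tip_y = x$tip_offset[2], tip_z = x$tip_offset[3],
    pivot_x = x$pivot_point[1], pivot_y = x$pivot_point[2],
    pivot_z = x$pivot_point[3],
    rms = x$rms, n_poses = x$n_poses
  )
}

#' @rdname tidy.pivot_calibration
#' @method glance pivot_calibration
#' @export
glance.pivot_calibration <- function(x, ...) {
  tibble::tibble(rms = x$rms, n_poses = x$n_poses)
}
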