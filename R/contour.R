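#' Nine-parameter contour parametrisation
#'
#' The central pipeline turning a digitised cartilage-contour point cloud
#' (expressed in its bone coordinate system, mm) into nine parameters:
#'
#' 1. total-least-squares plane fit of the 3D cloud;
#' 2. orthogonal projection of the cloud onto that plane;
#' 3. orthogonal-distance ellipse fit of the projected points, giving the
#'    major/minor axis lengths `L1 >= L2`;
#' 4. construction of the ellipse frame: X along the major axis, Z along the
#'    plane normal pointing laterally, Y = Z x X (along the minor axis);
#' 5. orthogonal projection of the *original* 3D cloud onto the plane whose
#'    normal is the ellipse minor axis;
#' 6. least-squares circle fit of that projection, giving the curvature
#'    radius `r`.
#'
#' The contour is then described by its position `T = (x, y, z)` (ellipse
#' centre in the bone frame, mm), orientation `R = (alpha, beta, gamma)`
#' (Cardan angles of the ellipse frame in the bone frame, degrees, intrinsic
#' X-Y'-Z''), the axis lengths `L1`, `L2` (mm) and the circle radius `r`
#' (mm). Left-sided clouds are mirrored to right-sided geometry first so
#' parameters are comparable across sides.
#'
#' Flat contours make the circle stage degenerate (the minor-axis projection
#' collapses onto a line); the result then carries `r = Inf` with
#' `circle_degenerate = TRUE` instead of failing.
#'
#' @param points Data frame/matrix with `x`, `y`, `z` in the bone frame (mm);
#'   at least 8 points spanning a non-degenerate loop.
#' @param laterality `"right"` (default) or `"left"`.
#' @param flat_r_threshold Optional radius cutoff (mm); fitted radii above it
#'   set the `flat` flag (off by default, mirroring the idea of screening
#'   flat cartilages by a curvature threshold).
#' @return An object of class `contour_parameters`; see [tidy()] for the
#'   one-row tabular form.
#' @examples
#' cloud <- generate_contour_cloud(
#'   list(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0,
#'        l1 = 28.8, l2 = 20.4, r = 38.1),
#'   n_points = 60, sigma_point = 0, seed = 1
#' )
#' parametrise_contour(cloud)
#' @export
parametrise_contour <- function(points, laterality = c("right", "left"),
                                flat_r_threshold = NULL) {
  laterality <- match.arg(laterality)
  m <- as_xyz_matrix(points)
  if (nrow(m) < 8) {
    abort_contract("Contour parametrisation needs at least 8 points.")
  }
  m <- mirror_to_right(m, laterality)

  plane <- with_stage("plane fit", fit_plane(m))
  uv <- project_to_plane(m, plane)
  efit <- with_stage("ellipse fit", fit_ellipse(uv))

  # ellipse frame in the bone frame
  normal <- lateral_sign(plane$normal)
  major3 <- as.numeric(plane$basis %*% efit$major_dir)
  X_e <- dominant_sign(major3)
  Z_e <- normal
  Y_e <- cross3(Z_e, X_e)
  R_e <- cbind(X_e, Y_e, Z_e)
  centre <- plane$centroid + as.numeric(plane$basis %*% efit$center)
  angles <- rotation_to_cardan(R_e)

  # circle stage: project the original cloud along the minor axis (Y_e)
  rel <- sweep(m, 2, centre)
  circ_uv <- cbind(u = rel %*% X_e, v = rel %*% Z_e)
  cfit <- tryCatch(
    fit_circle(circ_uv),
    contourfit_error_degenerate = function(e) NULL
  )
  circle_degenerate <- is.null(cfit)
  r <- if (circle_degenerate) Inf else cfit$radius

  structure(
    list(
      position = stats::setNames(centre, c("x", "y", "z")),
      angles = angles,
      l1 = efit$l1, l2 = efit$l2, r = r,
      residuals = c(
        plane = plane$rms_distance,
        ellipse = efit$rms_orthogonal_residual,
        circle = if (circle_degenerate) NA_real_ else cfit$rms_residual
      ),
      circle_degenerate = circle_degenerate,
      flat = !is.null(flat_r_threshold) && is.finite(r) && r > flat_r_threshold,
      gimbal_lock = isTRUE(attr(angles, "gimbal_lock")),
      frame = rigid_frame(centre, R_e),
      n = nrow(m),
      laterality = laterality,
      proj = list(
        ellipse_points = tibble::tibble(u = uv$u, v = uv$v),
        ellipse = efit,
        circle_points = tibble::tibble(u = circ_uv[, 1], v = circ_uv[, 2]),
        circle = cfit
      )
    ),
    class = "contour_parameters"
  )
}

# Sign of the lateral (medio-lateral) plane normal: positive third bone-frame
# coordinate, falling back to the anteroposterior then vertical axes when the
# contour plane contains the medio-lateral axis.
lateral_sign <- function(v) {
  for (i in c(3, 1, 2)) {
    if (abs(v[i]) > 1e-9) return(if (v[i] < 0) -v else v)
  }
  v
}

# Deterministic axis sign: positive along its dominant bone-frame component.
dominant_sign <- function(v) {
  k <- which.max(abs(v))
  if (v[k] < 0) -v else v
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      rlang::abort(sprintf("Contour parametrisation failed at stage: %s.", stage),
                   parent = e, class = "contourfit_error_stage")
    }
  )
}

#' @export
print.contour_parameters <- function(x, ...) {
  cat("<contour_parameters>\n")
  cat(sprintf("  T (mm):   %8.3f %8.3f %8.3f\n",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  R (deg):  %8.3f %8.3f %8.3f\n",
              x$angles[1], x$angles[2], x$angles[3]))
  cat(sprintf("  L1 %.3f mm, L2 %.3f mm, r %s mm\n", x$l1, x$l2,
              if (is.finite(x$r)) sprintf("%.3f", x$r) else "Inf (flat)"))
  cat(sprintf("  fit rms (mm): plane %.4g, ellipse %.4g, circle %s; n = %d\n",
              x$residuals[["plane"]], x$residuals[["ellipse"]],
              if (is.na(x$residuals[["circle"]])) "NA"
              else sprintf("%.4g", x$residuals[["circle"]]), x$n))
  invisible(x)
}

# Canonicalise an ellipse-frame rotation to the sign conventions used by
# parametrise_contour(); returns the rotation actually recoverable from data.
canonical_contour_rotation <- function(R) {
  X <- dominant_sign(R[, 1])
  Z <- lateral_sign(R[, 3])
  cbind(X, cross3(Z, X), Z)
}

#' Summarise a set of contour parametrisations
#'
#' Per-parameter sample mean, standard deviation (n - 1 denominator) and
#' large-sample 95% confidence interval of the mean
#' (mean +/- 1.96 sd / sqrt(n)), as reported when pooling digitalisations.
#'
#' @param contours A data frame with one row per contour holding the nine
#'   parameter columns (`x, y, z, alpha, beta, gamma, l1, l2, r`), e.g. from
#'   binding [tidy()] rows, or a list of `contour_parameters` objects.
#' @return A tibble with columns `parameter`, `n`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`.
#' @export
summarise_contours <- function(contours) {
  if (is.list(contours) && !is.data.frame(contours) &&
      all(vapply(contours, inherits, TRUE, "contour_parameters"))) {
    contours <- dplyr::bind_rows(lapply(contours, tidy))
  }
  params <- c("x", "y", "z", "alpha", "beta", "gamma", "l1", "l2", "r")
  missing <- setdiff(params, names(contours))
  if (length(missing) > 0) {
    abort_contract(sprintf("Missing parameter column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  if (nrow(contours) < 2) {
    abort_contract("Summaries need at least 2 contours.")
  }
  contours |>
    dplyr::select(dplyr::all_of(params)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      ci_lo = .data$mean - 1.96 * .data$sd / sqrt(.data$n),
      ci_hi = .data$mean + 1.96 * .data$sd / sqrt(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params)) |>
    dplyr::arrange(.data$parameter) |>
    dplyr::mutate(parameter = as.character(.data$parameter))
  }
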