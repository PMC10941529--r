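#' Least-squares circle fit
#'
#' Fits a circle to 2D points: the Kåsa algebraic solution (a linear least
#' squares in centre and radius) initialises a geometric refinement that
#' minimises the sum of squared radial residuals. The radius is profiled out
#' (the optimal radius for a fixed centre is the mean point-to-centre
#' distance), leaving a 2-parameter optimisation over the centre.
#'
#' @param points Data frame/matrix with in-plane coordinates `u`, `v` (or
#'   `x`, `y`), mm; at least 3 non-collinear points.
#' @param refine Refine the algebraic solution geometrically (default TRUE).
#' @param max_iter,tol Refinement controls (defaults 200, 1e-10).
#' @return An object of class `circle_fit`: `center` (length-2, mm),
#'   `radius` (mm), `rms_residual` (mm), `objective`, `n`.
#' @examples
#' fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
#' @export
fit_circle <- function(points, refine = TRUE, max_iter = 200, tol = 1e-10) {
  m <- as_uv_matrix(points)
  if (nrow(m) < 3) {
    abort_degenerate("Circle fitting needs at least 3 points.")
  }
  circle_check_collinear(m)
  x <- m[, 1]; y <- m[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) {
    abort_degenerate("Degenerate point configuration for circle fitting.")
  })
  center <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(center^2), 0))
  if (radius <= 0) abort_degenerate("Algebraic circle radius is not positive.")
  if (refine) {
    obj <- function(cc) {
      rho <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
      sum((rho - mean(rho))^2)
    }
    res <- stats::optim(center, obj, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    center <- res$par
    radius <- mean(sqrt((x - center[1])^2 + (y - center[2])^2))
  }
  resid <- sqrt((x - center[1])^2 + (y - center[2])^2) - radius
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean(resid^2)), objective = sum(resid^2),
         n = nrow(m)),
    class = "circle_fit"
  )
}

circle_check_collinear <- function(m, tol = 1e-9) {
  centred <- sweep(m, 2, colMeans(m))
  sv <- svd(centred)$d
  if (sv[2] / max(sv[1], 1e-12) < tol) {
    abort_degenerate("Points are collinear; the circle is not unique (flat contour).")
  }
  invisible(m)
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit> center (%.3f, %.3f) mm, r %.3f mm, rms %.4g mm (n = %d)\n",
    x$center[1], x$center[2], x$radius, x$rms_residual, x$n
  ))
  invisible(x)
}
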