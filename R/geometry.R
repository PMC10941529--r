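#' Rigid frames
#'
#' A rigid frame couples an origin (mm) with a right-handed orthonormal axis
#' triad. The axes are stored as the columns of a 3x3 rotation matrix, so a
#' point `p` expressed in the frame maps to the world as
#' `origin + axes %*% p`.
#'
#' @param origin Numeric length-3 origin, mm.
#' @param axes 3x3 rotation matrix; columns are the unit X, Y, Z directions.
#' @return An object of class `rigid_frame`.
#' @examples
#' rigid_frame(c(0, 0, 0), diag(3))
#' @export
rigid_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  if (length(origin) != 3 || any(!is.finite(origin))) {
    abort_contract("`origin` must be three finite numbers.")
  }
  check_rotation(axes)
  structure(list(origin = origin, axes = axes), class = "rigid_frame")
}

check_rotation <- function(R, tol = 1e-9, arg = "axes") {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || any(!is.finite(R))) {
    abort_contract(sprintf("`%s` must be a finite 3x3 matrix.", arg))
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    abort_contract(sprintf("`%s` is not orthonormal (tolerance %g).", arg, tol))
  }
  if (det(R) < 0) {
    abort_contract(sprintf("`%s` is left-handed (determinant < 0).", arg))
  }
  invisible(R)
}

#' @export
print.rigid_frame <- function(x, ...) {
  cat("<rigid_frame>\n origin:", format(x$origin, digits = 6), "\n")
  cat(" axes (columns X, Y, Z):\n")
  print(round(x$axes, 6))
  invisible(x)
}

frame_compose <- function(a, b) {
  # a then b applied to frame-b-local coordinates: world <- a ∘ b
  rigid_frame(a$origin + a$axes %*% b$origin, a$axes %*% b$axes)
}

frame_inverse <- function(f) {
  Rt <- t(f$axes)
  rigid_frame(-Rt %*% f$origin, Rt)
}

# Apply frame (local -> world) to an n x 3 matrix of points.
frame_apply <- function(f, m) {
  sweep(m %*% t(f$axes), 2, f$origin, "+")
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal point-to-plane
#' distances. The plane passes through the centroid of the points and its
#' normal is the smallest-variance principal direction of the centred cloud.
#'
#' @param points Data frame (or matrix) with columns `x`, `y`, `z` in mm;
#'   at least three non-collinear points.
#' @return An object of class `plane_fit` with elements `centroid`, `normal`
#'   (unit vector), `basis` (3x2 matrix of in-plane unit vectors) and
#'   `rms_distance` (mm).
#' @examples
#' pts <- tibble::tibble(x = runif(20), y = runif(20), z = 5)
#' fit_plane(pts)
#' @export
fit_plane <- function(points) {
  m <- as_xyz_matrix(points)
  if (nrow(m) < 3) {
    abort_degenerate("Plane fitting needs at least 3 points.")
  }
  centroid <- unname(colMeans(m))
  centred <- sweep(m, 2, centroid)
  sv <- svd(centred)
  # collinear (or coincident) points: second singular value vanishes
  scale_ref <- max(sv$d[1], 1e-12)
  if (sv$d[2] / scale_ref < 1e-10) {
    abort_degenerate("Points are collinear; the plane is not unique.")
  }
  normal <- sv$v[, 3]
  basis <- sv$v[, 1:2, drop = FALSE]
  rms <- sqrt(mean((centred %*% normal)^2))
  structure(
    list(centroid = centroid, normal = normal, basis = basis,
         rms_distance = rms, n = nrow(m)),
    class = "plane_fit"
  )
}

#' Orthogonal projection onto a plane
#'
#' Projects 3D points orthogonally onto a plane and returns their in-plane
#' coordinates in a caller-supplied (or plane-supplied) orthonormal basis.
#' The component along the plane normal is discarded.
#'
#' @param points Data frame/matrix with `x`, `y`, `z` (mm).
#' @param plane A [fit_plane()] result, or any list with `centroid`, `normal`
#'   and optionally `basis`.
#' @param basis 3x2 matrix of orthonormal in-plane direction vectors;
#'   defaults to `plane$basis`.
#' @return A tibble with in-plane coordinates `u`, `v` (mm).
#' @export
project_to_plane <- function(points, plane, basis = plane$basis) {
  m <- as_xyz_matrix(points)
  basis <- as.matrix(basis)
  if (any(dim(basis) != c(3, 2))) {
    abort_contract("`basis` must be a 3x2 matrix of in-plane unit vectors.")
  }
  G <- crossprod(basis)
  if (max(abs(G - diag(2))) > 1e-9 ||
      max(abs(crossprod(basis, plane$normal))) > 1e-9) {
    abort_contract("`basis` must be orthonormal and orthogonal to the plane normal.")
  }
  centred <- sweep(m, 2, plane$centroid)
  uv <- centred %*% basis
  tibble::tibble(u = uv[, 1], v = uv[, 2])
}

# Inverse of project_to_plane: lift in-plane coordinates back to 3D.
plane_unproject <- function(uv, plane, basis = plane$basis) {
  uv <- as_uv_matrix(uv)
  m <- uv %*% t(basis)
  xyz_tibble(sweep(m, 2, plane$centroid, "+"))
}

#' Cardan angle decomposition
#'
#' Decomposes a rotation matrix into intrinsic Cardan angles about the mobile
#' X-Y'-Z'' axes, in degrees: `R = Rx(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' This mobile-axis sequence is the common biomechanics convention for
#' reporting segment orientations.
#'
#' Near gimbal lock (`|beta| = 90` degrees) alpha and gamma are coupled; the
#' convention here sets `alpha = 0` and lets gamma absorb the free angle, and
#' the result carries a `gimbal_lock` flag.
#'
#' @param rotation A proper 3x3 rotation matrix.
#' @return A named numeric vector `c(alpha, beta, gamma)` in degrees, each in
#'   (-180, 180], with attribute `gimbal_lock` (logical).
#' @seealso [cardan_to_rotation()]
#' @export
rotation_to_cardan <- function(rotation) {
  R <- unname(as.matrix(rotation))
  check_rotation(R, arg = "rotation")
  sb <- max(-1, min(1, R[1, 3]))
  lock <- abs(sb) > 1 - 1e-12
  if (lock) {
    beta <- 90 * sign(sb)
    alpha <- 0
    gamma <- rad2deg(atan2(R[2, 1], R[2, 2]))
  } else {
    beta <- rad2deg(asin(sb))
    alpha <- rad2deg(atan2(-R[2, 3], R[3, 3]))
    gamma <- rad2deg(atan2(-R[1, 2], R[1, 1]))
  }
  out <- c(alpha = wrap_angle(alpha), beta = wrap_angle(beta),
           gamma = wrap_angle(gamma))
  attr(out, "gimbal_lock") <- lock
  out
}

#' Compose a rotation from Cardan angles
#'
#' Inverse of [rotation_to_cardan()]: builds
#' `Rx(alpha) %*% Ry(beta) %*% Rz(gamma)` (intrinsic X-Y'-Z'', degrees).
#'
#' @param alpha,beta,gamma Angles in degrees. `alpha` may also be a length-3
#'   vector holding all three.
#' @return A 3x3 rotation matrix.
#' @export
cardan_to_rotation <- function(alpha, beta = NULL, gamma = NULL) {
  if (length(alpha) == 3 && is.null(beta)) {
    beta <- alpha[[2]]; gamma <- alpha[[3]]; alpha <- alpha[[1]]
  }
  a <- deg2rad(alpha); b <- deg2rad(beta); g <- deg2rad(gamma)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# Uniformly distributed random rotation matrix (via random quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotation(q / vnorm(q))
}

quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

rotation_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / vnorm(q)
}

# Chordal mean of rotations: eigenvector of the quaternion outer-product sum,
# with quaternion signs aligned to the first rotation.
mean_rotation <- function(rotations) {
  qs <- lapply(rotations, rotation_to_quat)
  ref <- qs[[1]]
  M <- matrix(0, 4, 4)
  for (q in qs) {
    if (sum(q * ref) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  qbar <- eigen(M, symmetric = TRUE)$vectors[, 1]
  quat_to_rotation(qbar / vnorm(qbar))
}

# Geodesic angle (degrees) between two rotations.
rotation_angle_deg <- function(Ra, Rb = diag(3)) {
  R <- crossprod(Ra, Rb)
  cosang <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(max(-1, min(1, cosang))))
}
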