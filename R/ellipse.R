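#' Orthogonal-distance ellipse fit
#'
#' Fits an ellipse to 2D points by minimising the sum of squared orthogonal
#' (geometric) distances. A direct algebraic conic fit (Halir-Flusser variant
#' of the Fitzgibbon ellipse-specific fit) provides the initial estimate; a
#' quasi-Newton refinement of the 5-parameter geometric objective follows.
#' The reported axis lengths are full lengths (major axis length = 2a), as is
#' usual when describing anatomical contours.
#'
#' @param points Data frame/matrix with in-plane coordinates `u`, `v` (or
#'   `x`, `y`), mm; at least 5 points in non-degenerate position.
#' @param method `"orthogonal"` (default: algebraic init + geometric
#'   refinement) or `"algebraic"` (direct conic fit only).
#' @param max_iter Maximum refinement iterations (default 200).
#' @param tol Relative tolerance on the objective (default 1e-10).
#' @return An object of class `ellipse_fit`: `center` (length-2, mm), `l1`,
#'   `l2` (major/minor full axis lengths, mm, `l1 >= l2`), `major_dir`,
#'   `minor_dir` (unit 2-vectors), `rms_orthogonal_residual` (mm),
#'   `objective`, `converged`, `n`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 36)
#' fit_ellipse(cbind(14.4 * cos(t), 10.2 * sin(t)))
#' @export
fit_ellipse <- function(points, method = c("orthogonal", "algebraic"),
                        max_iter = 200, tol = 1e-10) {
  method <- match.arg(method)
  m <- as_uv_matrix(points)
  if (nrow(m) < 5) {
    abort_degenerate("Ellipse fitting needs at least 5 points.")
  }
  init <- ellipse_algebraic(m)
  geo <- init
  converged <- TRUE
  if (method == "orthogonal") {
    ref <- ellipse_refine(m, init, max_iter = max_iter, tol = tol)
    geo <- ref$par
    converged <- ref$converged
  }
  out <- ellipse_build(m, geo, converged)
  if (!converged) {
    rlang::abort(
      "Orthogonal-distance ellipse refinement did not converge; best iterate attached as `fit`.",
      class = "contourfit_error_convergence", fit = out
    )
  }
  out
}

# Assemble the ellipse_fit object from parameters (cx, cy, theta, a, b)
# with deterministic major-axis direction sign.
ellipse_build <- function(m, p, converged) {
  cx <- p[1]; cy <- p[2]; theta <- p[3]; a <- p[4]; b <- p[5]
  if (b > a) {            # enforce l1 >= l2 by swapping the axes
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  major <- c(cos(theta), sin(theta))
  # deterministic sign: positive first component (second if first is ~0)
  if (abs(major[1]) < 1e-12) {
    if (major[2] < 0) major <- -major
  } else if (major[1] < 0) {
    major <- -major
  }
  minor <- c(-major[2], major[1])
  d <- ellipse_distances(m, c(cx, cy, atan2(major[2], major[1]), a, b))
  structure(
    list(center = unname(c(cx, cy)), l1 = unname(2 * a), l2 = unname(2 * b),
         major_dir = major, minor_dir = minor,
         rms_orthogonal_residual = sqrt(mean(d^2)),
         objective = sum(d^2), converged = converged, n = nrow(m)),
    class = "ellipse_fit"
  )
}

# Direct ellipse-specific algebraic fit (Halir & Flusser partitioning),
# computed on centred/scaled coordinates for conditioning. Returns the
# geometric parameters (cx, cy, theta, a, b).
ellipse_algebraic <- function(m) {
  mu <- colMeans(m)
  s <- mean(sqrt(rowSums(sweep(m, 2, mu)^2)))
  if (s < 1e-12) abort_degenerate("Points are coincident; no conic fits them.")
  x <- (m[, 1] - mu[1]) / s
  y <- (m[, 2] - mu[2]) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    abort_degenerate("Degenerate point configuration for conic fitting.")
  })
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) {
    abort_degenerate("Algebraic conic solution is not an ellipse (hyperbolic/parabolic).")
  }
  a1 <- vec[, ok[1]]
  conic <- c(a1, T1 %*% a1)   # A x^2 + B xy + C y^2 + D x + E y + F (scaled frame)
  g <- conic_to_geometric(conic)
  # undo the centring/scaling
  unname(c(mu[1] + s * g[1], mu[2] + s * g[2], g[3], s * g[4], s * g[5]))
}

conic_to_geometric <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) abort_degenerate("Conic is not an ellipse.")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- rbind(c(A, B / 2), c(B / 2, C))
  e <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / e$values        # semi-axis^2 along each eigenvector
  if (any(ax2 <= 0)) abort_degenerate("Conic is not a real ellipse.")
  i <- which.max(ax2)
  vmax <- e$vectors[, i]
  c(cx, cy, atan2(vmax[2], vmax[1]), sqrt(max(ax2)), sqrt(min(ax2)))
}

# Exact orthogonal distances from points to the ellipse (cx, cy, theta, a, b).
# Nearest point found by safeguarded Newton on the perimeter angle,
# vectorised over points.
ellipse_distances <- function(m, p) {
  cx <- p[1]; cy <- p[2]; theta <- p[3]; a <- p[4]; b <- p[5]
  ct <- cos(theta); st <- sin(theta)
  dx <- m[, 1] - cx
  dy <- m[, 2] - cy
  u0 <- abs(ct * dx + st * dy)      # first-quadrant reduction
  v0 <- abs(-st * dx + ct * dy)
  t <- atan2(a * v0, b * u0)
  for (i in seq_len(40)) {
    stt <- sin(t); ctt <- cos(t)
    g <- (b^2 - a^2) * stt * ctt + a * u0 * stt - b * v0 * ctt
    gp <- (b^2 - a^2) * cos(2 * t) + a * u0 * ctt + b * v0 * stt
    step <- g / ifelse(abs(gp) < 1e-14, 1e-14, gp)
    step <- pmax(pmin(step, 0.5), -0.5)   # safeguard large Newton steps
    t <- pmin(pmax(t - step, 0), pi / 2)
    if (max(abs(step)) < 1e-14) break
  }
  sqrt((a * cos(t) - u0)^2 + (b * sin(t) - v0)^2)
}

ellipse_refine <- function(m, init, max_iter, tol) {
  # optimise over (cx, cy, theta, log a, log b) to keep axes positive
  obj <- function(q) {
    p <- c(q[1], q[2], q[3], exp(q[4]), exp(q[5]))
    sum(ellipse_distances(m, p)^2)
  }
  q0 <- c(init[1], init[2], init[3], log(init[4]), log(init[5]))
  res <- stats::optim(q0, obj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  list(
    par = c(res$par[1], res$par[2], res$par[3], exp(res$par[4]), exp(res$par[5])),
    converged = res$convergence == 0,
    value = res$value
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.3f, %.3f) mm, L1 %.3f mm, L2 %.3f mm, rms %.4g mm (n = %d)\n",
    x$center[1], x$center[2], x$l1, x$l2, x$rms_orthogonal_residual, x$n
  ))
  invisible(x)
}
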