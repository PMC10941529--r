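# Shared helpers for building geometric fixtures in code.

as_matrix_pts <- function(df) cbind(df$x, df$y, df$z)

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

# Points on an ellipse in the z = 0 plane, optionally posed in 3D.
ellipse_points_2d <- function(a, b, n = 36, theta = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * cos(t); v <- b * sin(t)
  cbind(u = center[1] + u * cos(theta) - v * sin(theta),
        v = center[2] + u * sin(theta) + v * cos(theta))
}

# Random contour parameters that are geometrically consistent and already in
# the canonical orientation branch recovered by parametrise_contour().
random_contour_params <- function() {
  l1 <- stats::runif(1, 18, 34)
  l2 <- stats::runif(1, 8, l1 - 2)
  r <- stats::runif(1, l1 / 2 + 2, 60)
  ang <- stats::runif(3, -60, 60)
  R <- contourfit:::canonical_contour_rotation(cardan_to_rotation(ang))
  ang <- rotation_to_cardan(R)
  list(x = stats::runif(1, -40, 40), y = stats::runif(1, -40, 40),
       z = stats::runif(1, -40, 40),
       alpha = ang[["alpha"]], beta = ang[["beta"]], gamma = ang[["gamma"]],
       l1 = l1, l2 = l2, r = r)
}

# Balanced long table drawn from the crossed random-effects model.
simulate_measurement_values <- function(n_cart, n_op, n_dig,
                                        s2_cart, s2_op, s2_dig, s2_res,
                                        mu = 0) {
  tb <- tidyr::expand_grid(cartilage_id = seq_len(n_cart),
                           operator_id = seq_len(n_op),
                           digitalisation = seq_len(n_dig))
  ce <- stats::rnorm(n_cart, 0, sqrt(s2_cart))
  oe <- stats::rnorm(n_op, 0, sqrt(s2_op))
  de <- stats::rnorm(n_dig, 0, sqrt(s2_dig))
  tb$value <- mu + ce[tb$cartilage_id] + oe[tb$operator_id] +
    de[tb$digitalisation] + stats::rnorm(nrow(tb), 0, sqrt(s2_res))
  tb
}

# Brute-force restricted-likelihood estimate of the four variance
# components, via direct optimisation of the dense REML criterion.
# Independent of the package's EMS/lme4 paths.
reml_brute_force <- function(tb, start = NULL) {
  if (is.null(start)) start <- rep(stats::var(tb$value) / 4, 4)
  y <- tb$value
  Zc <- stats::model.matrix(~ 0 + factor(tb$cartilage_id))
  Zo <- stats::model.matrix(~ 0 + factor(tb$operator_id))
  Zd <- stats::model.matrix(~ 0 + factor(tb$digitalisation))
  X <- matrix(1, length(y), 1)
  negreml <- function(p) {
    s <- exp(p)
    V <- s[1] * tcrossprod(Zc) + s[2] * tcrossprod(Zo) +
      s[3] * tcrossprod(Zd) + s[4] * diag(length(y))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    b <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% b
    as.numeric(2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                 crossprod(r, Vi %*% r))
  }
  o <- stats::optim(log(start), negreml, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, negreml, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  stats::setNames(exp(o$par),
                  c("cartilage", "operator", "digitalisation", "residual"))
}
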