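# Independent orthogonal distance used by the oracle checks: 1D golden
# section search over the perimeter angle, never the package's Newton path.
oracle_ellipse_objective <- function(m, cx, cy, theta, a, b) {
  ct <- cos(theta); st <- sin(theta)
  total <- 0
  for (i in seq_len(nrow(m))) {
    u0 <- ct * (m[i, 1] - cx) + st * (m[i, 2] - cy)
    v0 <- -st * (m[i, 1] - cx) + ct * (m[i, 2] - cy)
    d2 <- function(t) (a * cos(t) - u0)^2 + (b * sin(t) - v0)^2
    best <- Inf
    for (t0 in seq(0, 2 * pi, length.out = 9)[-9]) {
      o <- stats::optimize(d2, c(t0 - pi / 4, t0 + pi / 4), tol = 1e-12)
      best <- min(best, o$objective)
    }
    total <- total + best
  }
  total
}

test_that("noiseless ellipses are recovered exactly", {
  m <- ellipse_points_2d(14.4, 10.2, n = 36)
  fit <- fit_ellipse(m)
  expect_equal(fit$l1, 28.8, tolerance = 1e-9)
  expect_equal(fit$l2, 20.4, tolerance = 1e-9)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_lt(fit$rms_orthogonal_residual, 1e-9)
})

test_that("the circular limit gives equal axes and orthogonal directions", {
  m <- ellipse_points_2d(10, 10, n = 24)
  fit <- fit_ellipse(m)
  expect_equal(fit$l1, 20, tolerance = 1e-7)
  expect_equal(fit$l2, 20, tolerance = 1e-7)
  expect_lt(abs(sum(fit$major_dir * fit$minor_dir)), 1e-12)
})

test_that("axis order is enforced when the raw fit comes out reversed", {
  # nearly vertical major axis: the conic eigen-solution orders axes on its
  # own; output must still satisfy l1 >= l2 with deterministic signs
  m <- ellipse_points_2d(15, 8, n = 40, theta = pi / 2 + 0.05)
  fit <- fit_ellipse(m)
  expect_gte(fit$l1, fit$l2)
  expect_equal(fit$l1, 30, tolerance = 1e-7)
  expect_equal(fit$l2, 16, tolerance = 1e-7)
  expect_true(fit$major_dir[1] > 0 ||
                (abs(fit$major_dir[1]) < 1e-12 && fit$major_dir[2] > 0))
})

test_that("geometric refinement beats a local grid oracle on noisy data", {
  set.seed(5)
  truth <- list(cx = 2, cy = -1, theta = 0.4, a = 14.4, b = 10.2)
  m <- ellipse_points_2d(truth$a, truth$b, n = 100, theta = truth$theta,
                         center = c(truth$cx, truth$cy))
  m <- m + matrix(rnorm(200, 0, 0.2), ncol = 2)
  fit <- fit_ellipse(m)
  fit_obj <- oracle_ellipse_objective(
    m, fit$center[1], fit$center[2],
    atan2(fit$major_dir[2], fit$major_dir[1]), fit$l1 / 2, fit$l2 / 2
  )
  # 5-parameter grid around the generating truth
  grid_best <- Inf
  for (dc in c(-0.05, 0, 0.05)) for (dt in c(-0.005, 0, 0.005))
    for (da in c(-0.05, 0, 0.05)) for (db in c(-0.05, 0, 0.05)) {
      grid_best <- min(grid_best, oracle_ellipse_objective(
        m, truth$cx + dc, truth$cy + dc, truth$theta + dt,
        truth$a + da, truth$b + db
      ))
    }
  expect_lte(fit_obj, grid_best + 1e-8)
})

test_that("geometric objective never exceeds the algebraic initialisation", {
  set.seed(11)
  for (i in 1:5) {
    m <- ellipse_points_2d(runif(1, 10, 20), runif(1, 5, 9), n = 60,
                           theta = runif(1, 0, pi)) +
      matrix(rnorm(120, 0, 0.3), ncol = 2)
    alg <- fit_ellipse(m, method = "algebraic")
    geo <- fit_ellipse(m)
    expect_lte(geo$objective, alg$objective + 1e-10)
  }
})

test_that("ellipse parameters transform covariantly under rigid motion", {
  set.seed(13)
  m <- ellipse_points_2d(12, 7, n = 50) + matrix(rnorm(100, 0, 0.1), ncol = 2)
  fit0 <- fit_ellipse(m)
  phi <- 0.7; shift <- c(5, -3)
  Rot <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  fit1 <- fit_ellipse(sweep(m %*% t(Rot), 2, shift, "+"))
  expect_equal(fit1$l1, fit0$l1, tolerance = 1e-6)
  expect_equal(fit1$l2, fit0$l2, tolerance = 1e-6)
  expect_equal(fit1$center, as.numeric(Rot %*% fit0$center + shift),
               tolerance = 1e-6)
})

test_that("degenerate input raises a degenerate-conic error", {
  # collinear points admit no ellipse solution
  expect_error(fit_ellipse(cbind(1:8, 2 * (1:8))),
               class = "contourfit_error_degenerate")
  expect_error(fit_ellipse(matrix(1, 8, 2)),
               class = "contourfit_error_degenerate")
  expect_error(fit_ellipse(cbind(1:3, 1:3)),
               class = "contourfit_error_degenerate")
})

test_that("three-point circumcircle and noiseless circles are exact", {
  fit <- fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(fit$center, c(1, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)

  t <- seq(0, 2 * pi, length.out = 51)[-51]
  fit2 <- fit_circle(cbind(38.1 * cos(t), 38.1 * sin(t)))
  expect_equal(fit2$radius, 38.1, tolerance = 1e-9)
  expect_lt(fit2$rms_residual, 1e-9)
})

test_that("geometric circle refinement does not worsen the Kasa objective", {
  set.seed(17)
  t <- runif(50, 0, pi / 2)   # 90-degree arc
  m <- cbind(30 * cos(t), 30 * sin(t)) + matrix(rnorm(100, 0, 0.1), ncol = 2)
  kasa <- fit_circle(m, refine = FALSE)
  geo <- fit_circle(m)
  geo_obj <- sum((sqrt((m[, 1] - geo$center[1])^2 +
                         (m[, 2] - geo$center[2])^2) - geo$radius)^2)
  kasa_obj <- sum((sqrt((m[, 1] - kasa$center[1])^2 +
                          (m[, 2] - kasa$center[2])^2) - kasa$radius)^2)
  expect_lte(geo_obj, kasa_obj + 1e-10)
})

test_that("collinear points cannot define a circle", {
  expect_error(fit_circle(cbind(1:10, 2 * (1:10))),
               class = "contourfit_error_degenerate")
})
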