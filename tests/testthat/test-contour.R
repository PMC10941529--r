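test_that("zero-noise synthetic contours round-trip through the pipeline", {
  set.seed(31)
  for (i in 1:20) {
    truth <- random_contour_params()
    cloud <- generate_contour_cloud(truth, n_points = 80, sigma_point = 0)
    est <- tidy(parametrise_contour(cloud))
    expect_equal(c(est$x, est$y, est$z), c(truth$x, truth$y, truth$z),
                 tolerance = 1e-6)
    expect_equal(c(est$l1, est$l2), c(truth$l1, truth$l2), tolerance = 1e-6)
    expect_equal(est$r, truth$r, tolerance = 1e-3)
    expect_equal(c(est$alpha, est$beta, est$gamma),
                 c(truth$alpha, truth$beta, truth$gamma), tolerance = 1e-4)
  }
})

test_that("a flat contour flags the circle stage as degenerate", {
  m <- ellipse_points_2d(14.4, 10.2, n = 40)
  cloud <- tibble::tibble(x = m[, 1], y = m[, 2], z = 0)
  cp <- parametrise_contour(cloud)
  expect_true(cp$circle_degenerate)
  expect_identical(cp$r, Inf)
  expect_equal(unname(cp$position), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unclass(cp$angles), c(alpha = 0, beta = 0, gamma = 0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rigid displacement shifts the position and nothing else", {
  set.seed(32)
  truth <- random_contour_params()
  cloud <- generate_contour_cloud(truth, n_points = 60, sigma_point = 0.1,
                                  seed = 77)
  p0 <- tidy(parametrise_contour(cloud))
  shifted <- dplyr::mutate(cloud, x = x + 10, y = y - 5, z = z + 3)
  p1 <- tidy(parametrise_contour(shifted))
  expect_equal(c(p1$x, p1$y, p1$z), c(p0$x + 10, p0$y - 5, p0$z + 3),
               tolerance = 1e-9)
  expect_equal(c(p1$l1, p1$l2, p1$r), c(p0$l1, p0$l2, p0$r),
               tolerance = 1e-9)
})

test_that("mirrored-left and native-right clouds give equal parameters", {
  set.seed(33)
  truth <- random_contour_params()
  right <- generate_contour_cloud(truth, n_points = 64, sigma_point = 0,
                                  laterality = "right", seed = 5)
  left <- generate_contour_cloud(truth, n_points = 64, sigma_point = 0,
                                 laterality = "left", seed = 5)
  pr <- tidy(parametrise_contour(right, "right"))
  pl <- tidy(parametrise_contour(left, "left"))
  expect_equal(as.numeric(pr[1, 1:9]), as.numeric(pl[1, 1:9]),
               tolerance = 1e-9)
})

test_that("noisy recovery of the axis lengths is unbiased", {
  set.seed(34)
  truth <- list(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0,
                l1 = 28.8, l2 = 20.4, r = 38.1)
  ests <- t(vapply(1:100, function(i) {
    cloud <- generate_contour_cloud(truth, n_points = 120, sigma_point = 0.2)
    est <- tidy(parametrise_contour(cloud))
    c(est$l1, est$l2)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - truth$l1), 0.1)
  expect_lt(abs(mean(ests[, 2]) - truth$l2), 0.1)
})

test_that("too-small or degenerate clouds fail with stage labels", {
  expect_error(parametrise_contour(tibble::tibble(x = 1:5, y = 1, z = 1)),
               class = "contourfit_error_contract")
  line <- tibble::tibble(x = 1:10, y = 2 * (1:10), z = 3 * (1:10))
  expect_error(parametrise_contour(line), class = "contourfit_error_stage")
})

test_that("flat-cartilage screening flags large radii when enabled", {
  truth <- list(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0,
                l1 = 20, l2 = 12, r = 200)
  cloud <- generate_contour_cloud(truth, n_points = 60, sigma_point = 0,
                                  seed = 8)
  cp <- parametrise_contour(cloud, flat_r_threshold = 100)
  expect_true(cp$flat)
  cp2 <- parametrise_contour(cloud)
  expect_false(cp2$flat)
})

test_that("contour summaries match hand arithmetic and a direct oracle", {
  row <- function(l1) tibble::tibble(x = 0, y = 0, z = 0, alpha = 0, beta = 0,
                                     gamma = 0, l1 = l1, l2 = 10, r = 30)
  two <- dplyr::bind_rows(row(28), row(30))
  s <- summarise_contours(two)
  expect_equal(s$mean[s$parameter == "l1"], 29)
  expect_equal(s$sd[s$parameter == "l1"], sqrt(2))
  expect_equal(s$sd[s$parameter == "l2"], 0)
  expect_equal(s$ci_lo[s$parameter == "l2"], s$ci_hi[s$parameter == "l2"])

  set.seed(35)
  many <- dplyr::bind_rows(lapply(1:12, function(i) {
    tibble::tibble(x = rnorm(1), y = rnorm(1), z = rnorm(1), alpha = rnorm(1),
                   beta = rnorm(1), gamma = rnorm(1), l1 = rnorm(1, 28),
                   l2 = rnorm(1, 20), r = rnorm(1, 38))
  }))
  s2 <- summarise_contours(many)
  for (p in s2$parameter) {
    v <- many[[p]]
    expect_equal(s2$mean[s2$parameter == p], mean(v))
    expect_equal(s2$sd[s2$parameter == p], sd(v))
    expect_equal(s2$ci_hi[s2$parameter == p],
                 mean(v) + 1.96 * sd(v) / sqrt(length(v)))
  }
  expect_error(summarise_contours(row(28)),
               class = "contourfit_error_contract")
})
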