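test_that("noiseless between-specimen data loads all variance on cartilage", {
  tb <- tidyr::expand_grid(cartilage_id = 1:5, operator_id = 1:3,
                           digitalisation = 1:3)
  tb$value <- c(3, 7, 1, 9, 5)[tb$cartilage_id]
  vc <- estimate_variance_components(tb)
  expect_equal(vc$sigma2_operator, 0, tolerance = 1e-12)
  expect_equal(vc$sigma2_digitalisation, 0, tolerance = 1e-12)
  expect_equal(vc$sigma2_residual, 0, tolerance = 1e-12)
  expect_gt(vc$sigma2_cartilage, 0)
  # the cartilage component equals the between-cartilage variance of means
  expect_equal(vc$sigma2_cartilage, var(c(3, 7, 1, 9, 5)), tolerance = 1e-6)
  expect_equal(vc$sigma2_total,
               vc$sigma2_cartilage + vc$sigma2_operator +
                 vc$sigma2_digitalisation + vc$sigma2_residual)
})

test_that("EMS estimates recover generating components within 25%", {
  set.seed(51)
  tb <- simulate_measurement_values(50, 3, 3, 9, 1, 0.25, 0.25)
  vc <- estimate_variance_components(tb)
  expect_lt(abs(vc$sigma2_cartilage - 9) / 9, 0.25)
  expect_lt(abs(vc$sigma2_residual - 0.25) / 0.25, 0.25)
})

test_that("EMS equals a brute-force restricted-likelihood optimisation", {
  set.seed(52)
  for (i in 1:3) {
    tb <- simulate_measurement_values(6, 3, 3, 9, 2, 1, 0.3)
    ems <- estimate_variance_components(tb)
    if (any(ems$raw < 0.05)) next   # compare on interior solutions only
    bf <- reml_brute_force(tb)
    got <- c(ems$sigma2_cartilage, ems$sigma2_operator,
             ems$sigma2_digitalisation, ems$sigma2_residual)
    expect_lt(max(abs(got - unname(bf))), 1e-4)
    # and the packaged REML path agrees too
    reml <- estimate_variance_components(tb, method = "reml")
    expect_lt(abs(reml$sigma2_cartilage - ems$sigma2_cartilage), 1e-3)
  }
})

test_that("unbalanced designs are rejected by the EMS path but not REML", {
  set.seed(53)
  tb <- simulate_measurement_values(6, 3, 3, 4, 1, 0.5, 0.3)[-1, ]
  expect_error(estimate_variance_components(tb),
               class = "contourfit_error_contract")
  vc <- estimate_variance_components(tb, method = "reml")
  expect_identical(vc$method, "reml")
  expect_gt(vc$sigma2_cartilage, 0)
})

test_that("ICC formulas match hand arithmetic", {
  expect_equal(icc_intra(variance_components(9.5, 0, 0, 0.5)), 0.95)
  expect_equal(icc_intra(variance_components(4, 6, 0, 0)), 1)
  expect_equal(icc_intra(variance_components(0, 0, 5, 5)), 0)
  expect_equal(icc_inter(variance_components(9, 0.5, 0, 0.5)), 0.9)
  expect_equal(icc_inter(variance_components(7, 0, 3, 0)), 1)
  expect_equal(icc_inter(variance_components(1, 1, 1, 1)), 0.5)
  expect_error(icc_intra(variance_components(0, 0, 0, 0)),
               class = "contourfit_error_undefined")
})

test_that("SEM follows sqrt(total variance x (1 - ICC))", {
  vc <- variance_components(20, 2, 2, 1)   # total 25
  expect_equal(sem_from_icc(vc, 0.84), 2)
  expect_equal(sem_from_icc(vc, 1), 0)
  expect_equal(sem_from_icc(vc, 0), 5)
  expect_error(sem_from_icc(vc, 1.2), class = "contourfit_error_contract")
  # algebraic identity sem^2 + icc * total = total
  for (icc in c(-0.5, 0, 0.3, 0.97, 1)) {
    expect_equal(sem_from_icc(vc, icc)^2 + icc * vc$sigma2_total,
                 vc$sigma2_total, tolerance = 1e-12)
  }
})

test_that("the CI half-width reproduces published worked examples", {
  expect_equal(ci95_from_sem(3.0), 5.9)
  expect_equal(ci95_from_sem(2.3), 4.5)
  expect_equal(ci95_from_sem(1.6), 3.1)
  expect_equal(ci95_from_sem(5.4), 10.6)
  expect_equal(ci95_from_sem(0), 0)
})

test_that("classification bands are exact step functions at the thresholds", {
  expect_identical(classify_icc(0.68), "moderate")
  expect_identical(classify_icc(0.90), "excellent")
  expect_identical(classify_icc(0.49), "poor")
  eps <- 1e-12
  expect_identical(classify_icc(c(0.5 - eps, 0.5, 0.75 - eps, 0.75,
                                  0.9 - eps, 0.9)),
                   c("poor", "moderate", "moderate", "good", "good",
                     "excellent"))
  expect_identical(classify_sem(0.4), "excellent")
  expect_identical(classify_sem(3.0), "poor")
  expect_identical(classify_sem(1.5), "good")
  expect_identical(classify_sem(c(1 - eps, 1, 2 - eps, 2, 3 - eps, 3)),
                   c("excellent", "good", "good", "moderate", "moderate",
                     "poor"))
})

test_that("%SEM uses the absolute reference and rejects a zero reference", {
  expect_equal(sem_percent(0.4, -16.6), 100 * 0.4 / 16.6)
  expect_equal(round(sem_percent(0.4, -16.6), 1), 2.4)
  expect_equal(sem_percent(0, 5), 0)
  expect_error(sem_percent(1, 0), class = "contourfit_error_undefined")
})

test_that("a zero-noise study reports perfect reliability everywhere", {
  cfg <- study_config(seed = 101, n_specimens = 5, sigma_operator = 0,
                      sigma_digitalisation = 0, sigma_residual = 0,
                      points_per_contour = 40)
  st <- generate_study(cfg)
  rep <- reliability_report(st$measurement_table)
  expect_identical(nrow(rep), 18L)    # 9 parameters x 2 cartilage types
  expect_true(all(abs(rep$icc_intra - 1) < 1e-9))
  expect_true(all(abs(rep$icc_inter - 1) < 1e-9))
  expect_true(all(rep$sem_intra < 1e-6))
  expect_true(all(rep$icc_class_intra == "excellent"))
  expect_true(all(rep$sem_class_inter == "excellent"))
})

test_that("estimated ICCs concentrate around their plug-in values", {
  # components (9, 0.5, 0.25, 0.25): plug-in ICC_intra = 0.95,
  # ICC_inter = 0.925; a reduced replicate count keeps this check light,
  # the full 200-replicate version lives in the acceptance suite
  set.seed(54)
  reps <- t(vapply(1:40, function(i) {
    tb <- simulate_measurement_values(10, 3, 3, 9, 0.5, 0.25, 0.25)
    vc <- estimate_variance_components(tb)
    c(icc_intra(vc), icc_inter(vc))
  }, numeric(2)))
  expect_lt(abs(mean(reps[, 1]) - 0.95), 0.03)
  expect_lt(abs(mean(reps[, 2]) - 0.925), 0.03)
})

test_that("angle unwrapping stops the +/-180 cut from inflating variance", {
  set.seed(55)
  raw <- c(rnorm(20, 179, 1.5))
  wrapped <- ifelse(raw > 180, raw - 360, raw)   # values straddle the cut
  unwrapped <- contourfit:::unwrap_angles(wrapped)
  expect_lt(sd(unwrapped), 3)
  expect_gt(sd(wrapped), 30)
  expect_equal(sort(unwrapped %% 360), sort(wrapped %% 360), tolerance = 1e-9)

  # end to end: a gamma population near the cut still reports high ICC
  tb <- tidyr::expand_grid(cartilage_id = 1:6, operator_id = 1:3,
                           digitalisation = 1:3)
  truth <- rnorm(6, 179, 2)
  val <- truth[tb$cartilage_id] + rnorm(nrow(tb), 0, 0.2)
  tb$value <- ifelse(val > 180, val - 360, val)
  tb$cartilage_type <- "glenoid"; tb$parameter <- "gamma"; tb$unit <- "deg"
  rep <- reliability_report(tb)
  expect_gt(rep$icc_intra, 0.95)
})

test_that("ICC_intra dominates ICC_inter when operators vary more than trials", {
  set.seed(56)
  for (i in 1:20) {
    v <- sort(runif(2, 0, 3))   # sigma2_dig <= sigma2_op
    vc <- variance_components(runif(1, 1, 10), v[2], v[1], runif(1, 0, 2))
    expect_gte(icc_intra(vc) - icc_inter(vc), -1e-12)
  }
})
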