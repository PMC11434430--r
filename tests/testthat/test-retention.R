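test_that("rf_to_rm matches its closed form and rejects out-of-range input", {
  expect_identical(rf_to_rm(0.5), 0)
  expect_equal(rf_to_rm(0.25), log10(3), tolerance = 1e-12)
  expect_equal(rf_to_rm(0.25), 0.4771, tolerance = 1e-4)
  expect_equal(rf_to_rm(0.75), -rf_to_rm(0.25), tolerance = 1e-12)
  for (bad in list(0, 1, -0.1, 1.5, NA_real_, Inf)) {
    expect_error(rf_to_rm(bad), "strictly in")
  }
})

test_that("rf_to_rm is antisymmetric about 0.5 and inverts exactly", {
  x <- seq(0.01, 0.99, by = 0.01)
  expect_equal(rf_to_rm(1 - x), -rf_to_rm(x), tolerance = 1e-12)
  expect_equal(rm_to_rf(rf_to_rm(x)), x, tolerance = 1e-12)
  rm <- seq(-6, 6, by = 0.25)
  expect_equal(rf_to_rm(rm_to_rf(rm)), rm, tolerance = 1e-12)
})

test_that("fit_retention recovers a noiseless line exactly, in any row order", {
  cc <- c(10, 15, 20, 25, 30, 35)
  m <- data.frame(compound = "X", acetone_pct = cc,
                  rf = rm_to_rf(6.05 - 0.07 * cc))
  fit <- fit_retention(m)
  expect_equal(fit$rm0, 6.05, tolerance = 1e-10)
  expect_equal(fit$b, -0.07, tolerance = 1e-10)
  expect_equal(fit$r_abs, 1, tolerance = 1e-10)
  expect_equal(fit$residual_se, 0, tolerance = 1e-10)
  expect_equal(fit$n_points, 6L)

  shuffled <- m[sample(nrow(m)), ]
  fit2 <- fit_retention(shuffled)
  expect_equal(fit2[c("rm0", "b", "r_abs")], fit[c("rm0", "b", "r_abs")],
               tolerance = 1e-12)
})

test_that("fit_retention enforces its preconditions", {
  m <- data.frame(compound = "X", acetone_pct = c(10, 20, 30),
                  rf = c(0.3, 0.4, 0.5))
  expect_error(fit_retention(m[1:2, ]), ">= 3 distinct")
  expect_error(fit_retention(rbind(m, data.frame(compound = "Y",
                                                 acetone_pct = 15, rf = 0.2))),
               "single compound")
  same <- data.frame(compound = "X", acetone_pct = c(10, 20, 30), rf = 0.4)
  expect_error(fit_retention(same), "identical")
  # replicate spots at one concentration still need 3 distinct C values
  reps <- data.frame(compound = "X", acetone_pct = c(10, 10, 20),
                     rf = c(0.31, 0.29, 0.4))
  expect_error(fit_retention(reps), ">= 3 distinct")
})

test_that("replicate spots are averaged on the R_F scale before transforming", {
  cc <- c(10, 20, 30)
  rf <- rm_to_rf(2 - 0.05 * cc)
  m <- data.frame(compound = "X",
                  acetone_pct = rep(cc, each = 2),
                  rf = rep(rf, each = 2) + rep(c(-0.02, 0.02), 3))
  fit <- fit_retention(m)
  manual <- fit_retention(data.frame(compound = "X", acetone_pct = cc,
                                     rf = rf))
  expect_equal(fit$rm0, manual$rm0, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
})

test_that("low-correlation fits warn rather than fail", {
  set.seed(7)
  m <- data.frame(compound = "X", acetone_pct = seq(10, 60, 10),
                  rf = rm_to_rf(1 - 0.01 * seq(10, 60, 10) + rnorm(6, 0, 0.5)))
  expect_warning(fit_retention(m), "quality floor")
})

test_that("fit_calibration and fit_retention agree with a brute-force SSE oracle", {
  set.seed(101)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    x <- sort(runif(n, 0, 50))
    y <- runif(1, -2, 6) + runif(1, -0.2, 0.2) * x + rnorm(n, 0, 0.3)
    oracle <- brute_ols(x, y)
    cal <- fit_calibration(data.frame(name = letters[1:n], rm0 = x,
                                      logp_lit = y))
    expect_equal(cal$slope, oracle$slope, tolerance = 1e-6)
    expect_equal(cal$intercept, oracle$intercept, tolerance = 1e-6)
    ret <- suppressWarnings(
      fit_retention(data.frame(compound = "Z", acetone_pct = x,
                               rf = rm_to_rf(pmax(pmin(y, 6), -6)))))
    oracle_rm <- brute_ols(x, rf_to_rm(rm_to_rf(pmax(pmin(y, 6), -6))))
    expect_equal(ret$rm0, oracle_rm$intercept, tolerance = 1e-6)
    expect_equal(ret$b, oracle_rm$slope, tolerance = 1e-6)
  }
})

test_that("fit_calibration validates its standards", {
  expect_error(fit_calibration(data.frame(name = c("a", "b"), rm0 = 1:2,
                                          logp_lit = 2:3)), ">= 3")
  expect_error(fit_calibration(data.frame(name = letters[1:4], rm0 = 1,
                                          logp_lit = 1:4)), "zero variance")
  exact <- fit_calibration(data.frame(name = c("a", "b", "c"), rm0 = 0:2,
                                      logp_lit = 1:3))
  expect_equal(exact$slope, 1, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_abs, 1, tolerance = 1e-12)
})

test_that("predict_logp is the fitted affine map and preserves the fit correlation", {
  std <- load_fixture("table2_standards")
  curve <- fit_calibration(std)
  expect_equal(predict_logp(curve, 0), curve$intercept)
  preds <- predict_logp(curve, std$rm0)
  # predictions are an affine map of rm0, so their correlation with the
  # literature values equals the curve's |r|
  expect_equal(abs(cor(preds, std$logp_lit)), curve$r_abs, tolerance = 1e-12)
  expect_error(predict_logp(curve, NA_real_), "finite")
  expect_error(predict_logp(list(slope = 1), 1), "calibration_curve")
})

test_that("run_tlc_pipeline chains the stages and reports per compound", {
  std <- load_fixture("table2_standards")
  cc <- seq(65, 90, 5)
  truths <- c(A = 4.0, B = 6.05)
  m <- do.call(rbind, lapply(names(truths), function(id) {
    data.frame(compound = id, acetone_pct = cc,
               rf = rm_to_rf(truths[[id]] - 0.07 * cc))
  }))
  res <- run_tlc_pipeline(m, std)
  expect_s3_class(res, "tlc_pipeline")
  expect_equal(nrow(res$records), 2L)
  expect_equal(res$records$rm0, unname(truths), tolerance = 1e-9)
  # hand-computed through the printed coefficients
  hand_curve <- calibration_curve(1.1332, 0.6683)
  expect_equal(predict_logp(hand_curve, 4.0), 1.1332 * 4.0 + 0.6683)
  # pipeline predictions use its own fitted curve coefficients
  expect_equal(res$records$logp_tlc,
               res$curve$slope * res$records$rm0 + res$curve$intercept,
               tolerance = 1e-12)
  expect_error(run_tlc_pipeline(m[0, ], std), "no measurements")
  # stage errors carry the compound id
  bad <- rbind(m, data.frame(compound = "C", acetone_pct = c(10, 20),
                             rf = c(0.5, 0.6)))
  expect_error(run_tlc_pipeline(bad, std), "compound 'C'")
})

test_that("rounded reporting mirrors the conventional table precision", {
  std <- load_fixture("table2_standards")
  cc <- seq(65, 90, 5)
  m <- data.frame(compound = "X", acetone_pct = cc,
                  rf = rm_to_rf(6.049876 - 0.0713 * cc))
  res <- run_tlc_pipeline(m, std, round = TRUE)
  expect_equal(res$records$rm0, 6.05)
  expect_equal(res$records$b, -0.07)
  expect_equal(res$records$r_abs, 1)
})
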