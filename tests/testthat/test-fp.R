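test_that("fp_basis reproduces the closed forms, including the repeated-power rule", {
  expect_equal(unname(fp_basis(exp(1), 0)[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(fp_basis(2, -2)[1, 1]), 0.25, tolerance = 1e-12)
  b <- fp_basis(4, c(0.5, 0.5))
  expect_equal(unname(b[1, ]), c(2, 2 * log(4)), tolerance = 1e-12)
  b2 <- fp_basis(c(2, 3), c(-1, 2))
  expect_equal(unname(b2), cbind(c(1/2, 1/3), c(4, 9)), tolerance = 1e-12)
  # repeated power zero gives ln x and (ln x)^2
  b0 <- fp_basis(exp(2), c(0, 0))
  expect_equal(unname(b0[1, ]), c(2, 4), tolerance = 1e-12)
})

test_that("nonpositive exposures raise a domain error naming the offending count", {
  expect_error(fp_basis(c(1, 0, -3), 1), "2 exposure value",
               class = "vitdmr_domain_error")
  expect_error(fit_fp(rnorm(3), c(1, 2, -1), degree = 1),
               class = "vitdmr_domain_error")
})

test_that("noiseless fractional-polynomial relationships are recovered exactly", {
  x <- runif(2000, 15, 90)
  fit_log <- fit_fp(3 * log(x), x, degree = 1)
  expect_equal(fit_log$powers, 0)
  expect_equal(unname(fit_log$coefficients["ln(x)"]), 3, tolerance = 1e-6)
  expect_lt(fit_log$rss, 1e-12)

  fit_id <- fit_fp(2.5 * x + 1, x, degree = 1)
  expect_equal(fit_id$powers, 1)
  expect_equal(unname(fit_id$coefficients["x^1"]), 2.5, tolerance = 1e-6)
})

test_that("power selection finds the generating power under light noise", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      x <- runif(10000, 15, 90)
      y <- 2 * sqrt(x) + rnorm(10000, 0, 0.01)
      fit_fp(y, x, degree = 1)$powers == 0.5
    })
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("the selected fit attains the minimum deviance over its candidate class", {
  withr::with_seed(42, {
    x <- runif(500, 15, 90)
    y <- 0.05 * x - 20 / x + rnorm(500, 0, 0.5)
    covs <- data.frame(c1 = rnorm(500))
    best1 <- fit_fp(y, x, covs, degree = 1)
    for (p in fp_powers()) {
      expect_lte(best1$deviance,
                 fit_fp_powers(y, x, covs, powers = p, linear = FALSE)$deviance + 1e-8)
    }
    best2 <- fit_fp(y, x, covs, degree = 2)
    for (pair in list(c(-2, 0), c(0, 0), c(0.5, 3), c(1, 1), c(-0.5, 2))) {
      expect_lte(best2$deviance,
                 fit_fp_powers(y, x, covs, powers = pair)$deviance + 1e-8)
    }
    expect_lte(best2$deviance, best1$deviance + 1e-8)
  })
})

test_that("compare_fp applies the Royston df convention and handles edge cases", {
  withr::with_seed(7, {
    x <- runif(800, 15, 90)
    y <- 1 + 0.02 * x + rnorm(800)
    lin <- fit_fp_powers(y, x, powers = 1)
    fp1 <- fit_fp(y, x, degree = 1)
    fp2 <- fit_fp(y, x, degree = 2)
    expect_equal(compare_fp(lin, fp1)$df, 1L)
    expect_equal(compare_fp(fp1, fp2)$df, 2L)
    expect_equal(compare_fp(lin, fp2)$df, 3L)
    # identical fits: statistic 0, p = 1
    same <- compare_fp(fp1, fp1_copy <- fit_fp_powers(y, x, powers = fp1$powers,
                                                      linear = FALSE))
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)
    # mismatched n is incomparable
    lin_short <- fit_fp_powers(y[1:400], x[1:400], powers = 1)
    expect_error(compare_fp(lin_short, fp1), class = "vitdmr_incomparable_fits")
  })
})

test_that("the LR statistic is invariant to affine rescaling of covariate columns", {
  withr::with_seed(11, {
    x <- runif(1000, 15, 90)
    c1 <- rnorm(1000, 50, 10)
    y <- 3 * log(x) + 0.1 * c1 + rnorm(1000)
    t1 <- compare_fp(fit_fp_powers(y, x, data.frame(c1 = c1), powers = 1),
                     fit_fp(y, x, data.frame(c1 = c1), degree = 1))
    c1s <- (c1 - 50) / 10
    t2 <- compare_fp(fit_fp_powers(y, x, data.frame(c1 = c1s), powers = 1),
                     fit_fp(y, x, data.frame(c1 = c1s), degree = 1))
    expect_equal(t1$statistic, t2$statistic, tolerance = 1e-8)
  })
})

test_that("difference curves anchor at the reference and match closed forms", {
  x <- runif(3000, 15, 120)
  # exact linear model: difference is c * (x - ref)
  fit_lin <- fit_fp_powers(2 * x + 5, x, powers = 1)
  cv <- curve_from_fp(fit_lin, reference = 50, grid = c(25, 50, 75))
  expect_equal(cv$difference, 2 * (c(25, 50, 75) - 50), tolerance = 1e-8)
  expect_equal(cv$difference[cv$x == 50], 0)
  expect_equal(cv$se[cv$x == 50], 0)

  # noiseless log model: difference(100) = 3 ln 2
  fit_log <- fit_fp(3 * log(x), x, degree = 1)
  cv2 <- curve_from_fp(fit_log, reference = 50, grid = c(50, 100))
  expect_equal(cv2$difference[2], 3 * log(2), tolerance = 1e-8)

  expect_error(curve_from_fp(fit_log, reference = 50, grid = c(-5, 50)),
               class = "vitdmr_domain_error")
})

test_that("curve CIs are symmetric and widen with residual noise", {
  withr::with_seed(5, {
    x <- runif(4000, 15, 90)
    mu <- 3 * log(x)
    e <- rnorm(4000)
    grid <- c(20, 35, 65, 85)
    cv_lo <- curve_from_fp(fit_fp_powers(mu + 0.5 * e, x, powers = 0, linear = FALSE),
                           reference = 50, grid = grid)
    cv_hi <- curve_from_fp(fit_fp_powers(mu + 2 * e, x, powers = 0, linear = FALSE),
                           reference = 50, grid = grid)
    expect_equal(cv_lo$upper95 - cv_lo$difference,
                 cv_lo$difference - cv_lo$lower95, tolerance = 1e-10)
    expect_true(all(cv_hi$se > cv_lo$se))
  })
})
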