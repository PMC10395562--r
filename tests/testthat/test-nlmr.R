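test_that("doubly-ranked assignment matches the hand enumerations", {
  z <- 1:9
  # exposure rank equal to score position within each pre-stratum
  x_fwd <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  a_fwd <- doubly_ranked_strata(z, x_fwd, k = 3)
  expect_equal(as.integer(a_fwd), c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  expect_identical(which(a_fwd == 1), c(1L, 4L, 7L))
  expect_identical(which(a_fwd == 2), c(2L, 5L, 8L))
  expect_identical(which(a_fwd == 3), c(3L, 6L, 9L))

  # exposure reverse-ranked within each pre-stratum
  x_rev <- c(3, 2, 1, 3, 2, 1, 3, 2, 1)
  a_rev <- doubly_ranked_strata(z, x_rev, k = 3)
  expect_identical(which(a_rev == 1), c(3L, 6L, 9L))
  expect_identical(which(a_rev == 3), c(1L, 4L, 7L))
})

test_that("infeasible and remainder cases follow the documented rules", {
  expect_error(doubly_ranked_strata(1:5, 1:5, k = 10),
               class = "vitdmr_infeasible_stratification")
  z <- c(5, 1, 4, 2, 8, 7, 3, 9, 6, 10)
  expect_message(a <- doubly_ranked_strata(z, rev(z), k = 3), "dropped 1")
  expect_equal(attr(a, "dropped"), 1)
  expect_equal(sum(!is.na(a)), 9)
  expect_true(is.na(a[which(z == 10)]))  # highest-score remainder dropped
  expect_equal(as.integer(table(a)), c(3, 3, 3))
})

test_that("assignment equals the brute-force sort-and-deal oracle on random instances", {
  withr::with_seed(911, {
    for (r in 1:100) {
      k <- sample(c(2, 5, 10), 1)
      n <- sample(k:200, 1)
      z <- rnorm(n)
      x <- rnorm(n)
      a <- suppressMessages(doubly_ranked_strata(z, x, k))
      expect_identical(as.integer(a), oracle_strata(z, x, k))
    }
  })
})

test_that("stratum composition is invariant to permuting input rows", {
  withr::with_seed(19, {
    n <- 500
    z <- rnorm(n)
    x <- 0.4 * z + rnorm(n)
    a <- doubly_ranked_strata(z, x, k = 10)
    perm <- sample(n)
    a_perm <- doubly_ranked_strata(z[perm], x[perm], k = 10)
    expect_identical(as.integer(a_perm), as.integer(a)[perm])
  })
})

test_that("stratum mean exposure increases with stratum index under positive dependence", {
  withr::with_seed(23, {
    n <- 2000
    z <- rnorm(n)
    x <- z + rnorm(n, 0, 0.8)
    a <- doubly_ranked_strata(z, x, k = 20)
    means <- tapply(x, a, mean)
    expect_true(all(diff(means) > 0))
  })
})

test_that("LACE reduces to the constant effect when the outcome is an exact multiple of exposure", {
  withr::with_seed(29, {
    n <- 3000
    z <- rnorm(n)
    x <- 50 + 5 * z + rnorm(n, 0, 10)
    y <- 2 * x
    a <- doubly_ranked_strata(z, x, k = 10)
    # stratum-specific denominator: lace is exactly 2 in every stratum
    st_s <- lace_per_stratum(a, z, x, y, denominator = "stratum")
    expect_equal(st_s$lace, rep(2, 10), tolerance = 1e-8)
    # population denominator: exact only on average across strata
    st_p <- lace_per_stratum(a, z, x, y)
    expect_equal(mean(st_p$lace), 2, tolerance = 0.15)

    # doubling the outcome doubles every LACE and its SE
    st2 <- lace_per_stratum(a, z, x, 2 * y)
    expect_equal(st2$lace, 2 * st_p$lace, tolerance = 1e-10)
    expect_equal(st2$lace_se, 2 * st_p$lace_se, tolerance = 1e-10)
    expect_equal(sum(st_p$n), sum(!is.na(a)))
  })
})

test_that("strata too small for the adjusted regression are refused", {
  withr::with_seed(2, {
    z <- rnorm(100); x <- rnorm(100); y <- rnorm(100)
    a <- doubly_ranked_strata(z, x, k = 10)
    expect_error(suppressWarnings(lace_per_stratum(a, z, x, y, min_stratum_n = 30)),
                 class = "vitdmr_stratum_too_small")
  })
})

test_that("meta-regression recovers noiseless derivative laws and degenerate designs error", {
  st_log <- tibble::tibble(mean_x = seq(20, 90, length.out = 20),
                           lace = 3 / seq(20, 90, length.out = 20),
                           lace_se = 0.01)
  fit <- fp_meta_regression(st_log, degree = 1)
  expect_equal(fit$powers, 0)
  expect_equal(unname(fit$coefficients), 3, tolerance = 1e-6)

  # constant LACE: the linear causal model (power 1) fits with zero deviance
  st_const <- tibble::tibble(mean_x = seq(20, 90, length.out = 15),
                             lace = 0.04, lace_se = 0.02)
  fit_c <- fp_meta_regression(st_const, degree = 1)
  expect_equal(fit_c$powers, 1)
  expect_lt(fit_c$wdev, 1e-16)
  tt <- nonlinearity_test(st_const, fit_c)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  st_bad <- tibble::tibble(mean_x = rep(50, 12), lace = rnorm(12), lace_se = 1)
  expect_error(fp_meta_regression(st_bad), class = "vitdmr_degenerate_meta_design")
  expect_error(fp_meta_regression(st_log[1:5, ]), "at least 10 strata")
})

test_that("curve integration uses the closed-form antiderivatives", {
  st_const <- tibble::tibble(mean_x = seq(20, 90, length.out = 15),
                             lace = 0.04, lace_se = 0.02)
  fit_c <- fp_meta_regression(st_const, degree = 1)
  cv <- integrate_curve(fit_c, reference = 50, grid = c(20, 50, 90))
  expect_equal(cv$difference, 0.04 * (c(20, 50, 90) - 50), tolerance = 1e-8)
  expect_equal(cv$se[cv$x == 50], 0)

  st_log <- tibble::tibble(mean_x = seq(20, 90, length.out = 20),
                           lace = 3 / seq(20, 90, length.out = 20),
                           lace_se = 0.01)
  fit_l <- fp_meta_regression(st_log, degree = 1)
  cv2 <- integrate_curve(fit_l, reference = 50, grid = c(100))
  expect_equal(cv2$difference, 3 * log(2), tolerance = 1e-6)

  expect_error(integrate_curve(fit_l, grid = c(0, 10)),
               class = "vitdmr_domain_error")
})

test_that("under linear truth the integrated curve and linear MR agree on the 25-75 difference", {
  co <- male_cohort(100000, seed = 71, causal_fn = causal_linear(0.01))
  nl <- run_nonlinear_mr(co, k = 100, grid = c(25, 75))
  d_nl <- diff(nl$curve$difference)           # h(75) - h(25)
  d_lin <- 2 * nl$linear$beta_per_25          # 50 nmol/L on the linear scale
  se <- 2 * nl$linear$se_per_25
  expect_lt(abs(d_nl - d_lin), 3 * se)
  expect_equal(nl$strata$n, rep(1000, 100))
})
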