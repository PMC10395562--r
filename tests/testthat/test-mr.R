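test_that("the weighted score is the weighted average of oriented dosages", {
  inst <- instrument_spec(c("a", "b", "c"), c("A", "C", "G"),
                          c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5))
  g1 <- tibble::tibble(a = 0, b = 1, c = 2)
  expect_equal(weighted_score(g1, inst), 0.8 / 0.6)

  g0 <- tibble::tibble(a = 0, b = 0, c = 0)
  expect_equal(weighted_score(g0, inst), 0)

  # scale invariance of the average
  inst10 <- instrument_spec(c("a", "b", "c"), c("A", "C", "G"),
                            10 * c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5))
  g <- tibble::tibble(a = c(0, 1, 2), b = c(2, 1, 0), c = c(1, 1, 1))
  expect_equal(weighted_score(g, inst), weighted_score(g, inst10))

  # a negative weight flips the dosage (g -> 2 - g) and the weight sign
  inst_neg <- instrument_spec(c("a", "b"), c("A", "C"), c(0.2, -0.3), c(0.4, 0.4))
  inst_pos <- instrument_spec(c("a", "b"), c("A", "C"), c(0.2, 0.3), c(0.4, 0.4))
  gg <- tibble::tibble(a = c(0, 1, 2), b = c(0, 1, 2))
  flipped <- tibble::tibble(a = gg$a, b = 2 - gg$b)
  expect_equal(weighted_score(gg, inst_neg), weighted_score(flipped, inst_pos))

  expect_error(weighted_score(tibble::tibble(a = 1), inst),
               class = "vitdmr_instrument_mismatch")
})

test_that("first-stage diagnostics behave at the exact and null extremes", {
  withr::with_seed(21, {
    z <- rnorm(2000)
    fs <- first_stage(z, 2 * z)
    expect_equal(fs$r2_partial, 1, tolerance = 1e-10)
    expect_gt(fs$f, 1e10)

    x <- rnorm(2000)
    fs0 <- first_stage(sample(z), x)
    expect_lt(fs0$r2_partial, 3 / sqrt(2000))  # ~3 SE of zero
    expect_lt(abs(fs0$beta_zx / fs0$se), 3)

    expect_error(first_stage(rep(1, 10), rnorm(10)),
                 class = "vitdmr_degenerate_instrument")
  })
})

test_that("the Wald ratio equals two-stage least squares with a single instrument", {
  withr::with_seed(8, {
    n <- 1500
    z <- rnorm(n)
    x <- 40 + 4 * z + rnorm(n, 0, 8)
    y <- 20 + 0.05 * x + rnorm(n)
    mr <- linear_mr(z, x, y)
    expect_equal(mr$beta_per_unit, tsls_beta(z, x, y), tolerance = 1e-8)

    # ratio is invariant to rescaling the instrument
    mr_scaled <- linear_mr(-3.7 * z, x, y)
    expect_equal(mr$beta_per_unit, mr_scaled$beta_per_unit, tolerance = 1e-10)
    expect_equal(mr$se_per_unit, mr_scaled$se_per_unit, tolerance = 1e-10)
    expect_equal(mr$ci95, mr_scaled$ci95, tolerance = 1e-10)

    # reported per 25 nmol/L with a symmetric normal CI
    expect_equal(mr$beta_per_25, 25 * mr$beta_per_unit)
    expect_equal(mr$ci95, mr$beta_per_25 + c(-1, 1) * qnorm(.975) * mr$se_per_25)
  })
})

test_that("weak instruments trigger the delta-method warning", {
  withr::with_seed(33, {
    n <- 120
    z <- rnorm(n)
    x <- 0.05 * z + rnorm(n)
    y <- rnorm(n)
    expect_warning(linear_mr(z, x, y), "F = ")
  })
})

test_that("MR estimate is invariant to adding covariate-explained noise to the exposure", {
  withr::with_seed(14, {
    n <- 5000
    z <- rnorm(n)
    c1 <- rnorm(n)
    x <- 30 + 3 * z + rnorm(n, 0, 5)
    y <- 0.1 * x + rnorm(n)
    covs <- data.frame(c1 = c1)
    mr1 <- linear_mr(z, x, y, covs)
    mr2 <- linear_mr(z, x + 4 * c1, y, covs)  # covariate-explained shift in X
    expect_equal(mr1$beta_per_unit, mr2$beta_per_unit, tolerance = 1e-8)
  })
})

test_that("confounder scan flags planted pleiotropy and degenerate columns", {
  co <- male_cohort(20000, seed = 17, pleiotropy_bmi = 0.5)
  scan <- confounder_scan(co)
  expect_lt(scan$p[scan$confounder == "bmi"], 1e-3)
  expect_equal(scan$type[scan$confounder == "smoking"], "categorical")

  co$flat <- 1
  scan2 <- confounder_scan(co, confounders = c("bmi", "flat"))
  expect_match(scan2$note[scan2$confounder == "flat"], "degenerate")
  expect_true(is.na(scan2$p[scan2$confounder == "flat"]))

  # without a planted path, the instrument-BMI association is unremarkable
  co0 <- male_cohort(20000, seed = 18)
  expect_gt(confounder_scan(co0)$p[1], 1e-3)
})
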