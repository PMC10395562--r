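#' Age bands used by the age-stratified analysis
#'
#' Fixed bands approximating population fourths: `<50`, `50-59`, `60-64`,
#' `65+`, closed on the left with integer ages (so 50 falls in the second
#' band and 65 in the fourth).
#'
#' @param age Numeric ages in years.
#' @return A factor with levels `<50`, `50-59`, `60-64`, `65+`.
#' @examples
#' age_band(c(49, 50, 59, 60, 64, 65))
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 50, 60, 65, Inf), right = FALSE,
      labels = c("<50", "50-59", "60-64", "65+"))
}

#' Sex-specific observational dose-response analysis
#'
#' The cross-sectional arm: within one sex, regresses grip strength on a
#' fractional polynomial of 25(OH)D adjusting for month of blood draw
#' (12-level factor), vitamin D supplementation, age, smoking status, BMI and
#' Townsend deprivation. The best FP2 is compared with the best FP1 (2 df);
#' the winner is then compared with the linear model, and that p-value is
#' reported as `p_nonlinear` (p < .05 read as a nonlinear association). The
#' returned curve comes from the selected model (linear when nonlinearity is
#' not supported), anchored at the reference exposure.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] for the layout).
#'   May contain both sexes; rows are filtered to `sex`.
#' @param sex `"male"` or `"female"`.
#' @param reference Reference 25(OH)D in nmol/L (default 50).
#' @param grid Exposure grid for the curve (default 15-90 nmol/L by 1).
#' @param min_n Minimum rows required (default 500).
#' @param alpha Significance level for the FP2-vs-FP1 and FP-vs-linear
#'   cascade (default 0.05).
#' @return A list of class `obs_result`: `fit` (selected `fp_fit`),
#'   `fits` (linear/fp1/fp2), `p_nonlinear`, `test_nonlinear`,
#'   `test_fp2_vs_fp1` ([compare_fp()] results), `curve`, `sex`, `n`.
#' @export
run_observational <- function(cohort, sex, reference = 50,
                              grid = seq(15, 90, by = 1),
                              min_n = 500, alpha = 0.05) {
  check_sex(sex)
  data <- filter_sex(cohort, sex)
  cols <- c("vitd", "grip", "month_of_draw", "supplement", "age",
            "smoking", "bmi", "townsend")
  check_columns(data, cols)
  if (nrow(data) < min_n) {
    abort(paste0("insufficient data: ", nrow(data), " ", sex,
                 " rows (< ", min_n, ")"),
          class = "vitdmr_insufficient_data")
  }
  check_complete(data, cols)

  y <- data$grip
  x <- data$vitd
  covs <- observational_covariates(data)

  fit_linear <- fit_fp_powers(y, x, covs, powers = 1, linear = TRUE)
  fit_fp1 <- fit_fp(y, x, covs, degree = 1)
  fit_fp2 <- fit_fp(y, x, covs, degree = 2)

  test_fp2_fp1 <- compare_fp(fit_fp1, fit_fp2)
  best_fp <- if (test_fp2_fp1$p < alpha) fit_fp2 else fit_fp1
  test_nonlinear <- compare_fp(fit_linear, best_fp)
  selected <- if (test_nonlinear$p < alpha) best_fp else fit_linear

  structure(
    list(
      sex = sex,
      n = nrow(data),
      fit = selected,
      fits = list(linear = fit_linear, fp1 = fit_fp1, fp2 = fit_fp2),
      test_fp2_vs_fp1 = test_fp2_fp1,
      test_nonlinear = test_nonlinear,
      p_nonlinear = test_nonlinear$p,
      reference = reference,
      curve = curve_from_fp(selected, reference = reference, grid = grid)
    ),
    class = "obs_result"
  )
}

#' Age-stratified observational analysis with interaction test
#'
#' Refits the sex-specific functional form selected by [run_observational()]
#' within each of the four fixed [age_band()]s (age is retained as a
#' continuous covariate within bands), and tests whether the dose-response
#' differs by age: a likelihood-ratio comparison of the pooled model (FP
#' terms + covariates + band main effects) against the model adding
#' band-by-FP-term interactions, with `3 x (number of FP terms)` degrees of
#' freedom.
#'
#' @inheritParams run_observational
#' @return A list of class `obs_age_result`: `curves` (tibble of per-band
#'   curves with a `band` column), `interaction` (an `lr_test`), `bands`
#'   (per-band n), `pooled` (the pooled `obs_result`).
#' @export
run_age_stratified <- function(cohort, sex, reference = 50,
                               grid = seq(15, 90, by = 1),
                               min_n = 500, alpha = 0.05) {
  pooled <- run_observational(cohort, sex, reference = reference, grid = grid,
                              min_n = min_n, alpha = alpha)
  data <- filter_sex(cohort, sex)
  band <- age_band(data$age)
  y <- data$grip
  x <- data$vitd
  covs <- observational_covariates(data)
  powers <- pooled$fit$powers
  is_linear <- pooled$fit$label == "linear"

  curves <- list()
  counts <- table(band)
  for (b in levels(band)) {
    idx <- which(band == b)
    if (length(idx) < 2) {
      warn(paste0("age band ", b, " is empty or near-empty; skipped"))
      next
    }
    fit_b <- fit_fp_powers(y[idx], x[idx],
                           droplevels_covs(covs[idx, , drop = FALSE]),
                           powers = powers, linear = is_linear)
    cv <- curve_from_fp(fit_b, reference = reference, grid = grid)
    cv$band <- b
    curves[[b]] <- cv
  }

  ## interaction test on the pooled sex-specific sample
  band <- droplevels(band)
  if (nlevels(band) < 2) {
    warn("fewer than two non-empty age bands; interaction test not possible")
    return(structure(
      list(sex = sex, pooled = pooled,
           bands = tibble::tibble(band = names(counts), n = as.integer(counts)),
           curves = dplyr::bind_rows(curves), interaction = NULL),
      class = "obs_age_result"
    ))
  }
  B <- fp_basis(x, powers)
  Xcov <- covariate_matrix(covs)
  D <- model.matrix(~band)[, -1, drop = FALSE]
  inter <- do.call(cbind, lapply(seq_len(ncol(B)), function(k) {
    M <- D * B[, k]
    colnames(M) <- paste0(colnames(D), ":", colnames(B)[k])
    M
  }))
  X0 <- cbind(`(Intercept)` = 1, B, Xcov, D)
  X1 <- cbind(X0, inter)
  f0 <- ols_fit(X0, y)
  f1 <- ols_fit(X1, y)
  interaction <- lr_test(f0$deviance - f1$deviance, df = ncol(inter))

  structure(
    list(
      sex = sex,
      pooled = pooled,
      bands = tibble::tibble(band = names(counts), n = as.integer(counts)),
      curves = dplyr::bind_rows(curves),
      interaction = interaction
    ),
    class = "obs_age_result"
  )
}

droplevels_covs <- function(covs) {
  covs$month <- droplevels(covs$month)
  covs$smoking <- droplevels(covs$smoking)
  covs
}

#' @export
print.obs_result <- function(x, ...) {
  cat("<obs_result> observational dose-response,", x$sex,
      paste0("(n = ", x$n, ")\n"))
  cat("  selected model:", x$fit$label,
      if (x$fit$label != "linear")
        paste0("with powers (", paste(x$fit$powers, collapse = ", "), ")"),
      "\n")
  cat(sprintf("  p_nonlinear = %.4g (LR statistic %.3f on %d df)\n",
              x$p_nonlinear, x$test_nonlinear$statistic, x$test_nonlinear$df))
  invisible(x)
}

#' @export
tidy.obs_result <- function(x, ...) tidy(x$fit)

#' @export
glance.obs_result <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    n = x$n,
    model = x$fit$label,
    powers = paste(x$fit$powers, collapse = ","),
    p_nonlinear = x$p_nonlinear
  )
}

#' @export
glance.obs_age_result <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    p_interaction = x$interaction$p,
    statistic = x$interaction$statistic,
    df = x$interaction$df
  )
}
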