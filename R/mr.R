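#' First-stage regression of exposure on the allele score
#'
#' OLS of 25(OH)D on the weighted allele score plus covariates. Reports the
#' score coefficient, its standard error, the incremental (partial) R-squared
#' of the score beyond the covariates, and the partial F statistic (the
#' squared t of the score term, 1 numerator df).
#'
#' @param z Score vector.
#' @param x Exposure vector (nmol/L).
#' @param covariates Optional data frame/matrix of adjustment columns
#'   (month of draw, supplementation, genetic principal components).
#' @return A list of class `first_stage`: `beta_zx`, `se`, `r2_partial`, `f`,
#'   `n`.
#' @export
first_stage <- function(z, x, covariates = NULL) {
  stopifnot(length(z) == length(x))
  if (!is.finite(sd(z)) || sd(z) == 0) {
    abort("degenerate instrument: the score has no variation",
          class = "vitdmr_degenerate_instrument")
  }
  Xcov <- covariate_matrix(covariates)
  X0 <- cbind(`(Intercept)` = rep(1, length(x)), Xcov)
  X1 <- cbind(X0[, 1, drop = FALSE], z = z, Xcov)
  f0 <- ols_fit(X0, x)
  f1 <- ols_fit(X1, x)
  V <- ols_vcov(f1)
  beta <- unname(f1$coef["z"])
  se <- sqrt(V["z", "z"])
  structure(
    list(
      beta_zx = beta,
      se = se,
      r2_partial = max(0, (f0$rss - f1$rss) / f0$rss),
      f = (beta / se)^2,
      n = length(x)
    ),
    class = "first_stage"
  )
}

#' Linear Mendelian randomization via the Wald ratio
#'
#' The ratio of the covariate-adjusted score-outcome coefficient to the
#' score-exposure coefficient; with a single (score) instrument this equals
#' the two-stage least-squares estimate. The standard error is the
#' first-order delta method treating the denominator as fixed,
#' `se = |1/beta_zx| * se_zy`, which is accurate in the very strong instrument
#' regime this analysis targets; a warning is emitted when the first-stage
#' F falls below 10. The estimate is reported per 25 nmol/L of genetically
#' proxied 25(OH)D, as in the headline analysis.
#'
#' @inheritParams first_stage
#' @param y Outcome vector (grip strength, kg).
#' @param beta_zx_tol Smallest admissible |first-stage coefficient|.
#' @return A list of class `mr_result`: `beta_per_25`, `se_per_25`, `ci95`
#'   (per 25 nmol/L), `beta_per_unit`, `se_per_unit`, `first_stage_r2`,
#'   `f_statistic`, `n`.
#' @export
linear_mr <- function(z, x, y, covariates = NULL, beta_zx_tol = 1e-10) {
  stopifnot(length(z) == length(x), length(z) == length(y))
  fs <- first_stage(z, x, covariates)
  if (abs(fs$beta_zx) < beta_zx_tol) {
    abort("weak denominator: first-stage coefficient is numerically zero",
          class = "vitdmr_weak_denominator")
  }
  if (fs$f < 10) {
    warn(sprintf(paste0("first-stage F = %.2f (< 10): the fixed-denominator ",
                        "delta-method SE is unreliable for weak instruments"),
                 fs$f))
  }
  Xcov <- covariate_matrix(covariates)
  X1 <- cbind(`(Intercept)` = rep(1, length(y)), z = z, Xcov)
  f1 <- ols_fit(X1, y)
  V <- ols_vcov(f1)
  beta_zy <- unname(f1$coef["z"])
  se_zy <- sqrt(V["z", "z"])
  beta <- beta_zy / fs$beta_zx
  se <- se_zy / abs(fs$beta_zx)
  z975 <- qnorm(0.975)
  structure(
    list(
      beta_per_25 = 25 * beta,
      se_per_25 = 25 * se,
      ci95 = 25 * c(beta - z975 * se, beta + z975 * se),
      beta_per_unit = beta,
      se_per_unit = se,
      beta_zy = beta_zy,
      se_zy = se_zy,
      beta_zx = fs$beta_zx,
      first_stage_r2 = fs$r2_partial,
      f_statistic = fs$f,
      n = length(y)
    ),
    class = "mr_result"
  )
}

#' Linear MR on a cohort table
#'
#' Convenience wrapper: filters to one sex, derives the weighted allele score
#' from genotype columns when a `score` column is absent, and runs
#' [linear_mr()] adjusted for month of blood draw, supplementation and the
#' 10 genetic principal components.
#'
#' @param cohort A cohort tibble.
#' @param sex `"male"`, `"female"`, or `NULL` for the whole table.
#' @param instrument An [instrument_spec()], needed only when `score` is not
#'   already a column.
#' @return An `mr_result`.
#' @export
run_linear_mr <- function(cohort, sex = NULL, instrument = NULL) {
  data <- filter_sex(cohort, sex)
  z <- cohort_score(data, instrument)
  linear_mr(z, data$vitd, data$grip, mr_covariates(data))
}

cohort_score <- function(data, instrument = NULL) {
  if ("score" %in% names(data)) return(as.numeric(data$score))
  if (is.null(instrument)) {
    abort("cohort has no `score` column; supply `instrument` to derive it")
  }
  weighted_score(data, instrument)
}

#' Scan the instrument for confounder associations
#'
#' Pleiotropy diagnostic: regresses each potential confounder on the score.
#' Numeric confounders report the slope, SE and two-sided p-value; categorical
#' confounders report a global F test (one-way comparison of score means
#' across levels). Raw p-values, no multiplicity adjustment. Constant columns
#' are flagged as degenerate and excluded from testing.
#'
#' @param cohort A cohort tibble with a `score` column (or genotypes +
#'   `instrument`).
#' @param confounders Column names to scan.
#' @param instrument Optional [instrument_spec()] when `score` is absent.
#' @return A tibble: `confounder`, `type`, `beta`, `se`, `statistic`, `p`,
#'   `note`.
#' @export
confounder_scan <- function(cohort,
                            confounders = c("age", "bmi", "townsend", "smoking"),
                            instrument = NULL) {
  check_columns(cohort, confounders)
  z <- cohort_score(cohort, instrument)
  rows <- lapply(confounders, function(name) {
    v <- cohort[[name]]
    if (is.numeric(v) && length(unique(v)) > 1) {
      X <- cbind(`(Intercept)` = rep(1, length(z)), z = z)
      fit <- ols_fit(X, v)
      V <- ols_vcov(fit)
      beta <- unname(fit$coef["z"])
      se <- sqrt(V["z", "z"])
      tstat <- beta / se
      tibble::tibble(confounder = name, type = "numeric",
                     beta = beta, se = se, statistic = tstat,
                     p = 2 * stats::pt(-abs(tstat), df = fit$df_residual),
                     note = NA_character_)
    } else if (length(unique(v)) > 1) {
      f <- factor(v)
      a <- stats::anova(lm(z ~ f))
      tibble::tibble(confounder = name, type = "categorical",
                     beta = NA_real_, se = NA_real_,
                     statistic = a$`F value`[1], p = a$`Pr(>F)`[1],
                     note = NA_character_)
    } else {
      tibble::tibble(confounder = name, type = class(v)[1],
                     beta = NA_real_, se = NA_real_,
                     statistic = NA_real_, p = NA_real_,
                     note = "degenerate: constant column, excluded")
    }
  })
  dplyr::bind_rows(rows)
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result> linear MR (Wald ratio, weighted allele score)\n")
  cat(sprintf("  %.3f kg (95%% CI %.3f, %.3f) per 25 nmol/L 25(OH)D\n",
              x$beta_per_25, x$ci95[1], x$ci95[2]))
  cat(sprintf("  first-stage R2 = %.3f%%, F = %.1f, n = %d\n",
              100 * x$first_stage_r2, x$f_statistic, x$n))
  invisible(x)
}

#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(
    term = "25(OH)D (per 25 nmol/L)",
    estimate = x$beta_per_25,
    std.error = x$se_per_25,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2]
  )
}

#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    first_stage_r2 = x$first_stage_r2,
    f_statistic = x$f_statistic,
    n = x$n
  )
}
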