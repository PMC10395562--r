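#' Doubly-ranked stratification
#'
#' Partitions the sample into `k` strata with varying exposure but comparable
#' instrument distributions: individuals are first sorted by the allele score
#' into consecutive pre-strata of `k` members each (`Q = floor(N/k)` complete
#' pre-strata; the incomplete remainder is dropped and counted), then within
#' each pre-stratum the individual with the j-th smallest exposure is dealt to
#' stratum j. Each complete stratum therefore has exactly `Q` members. Ties in
#' score or exposure are broken by original row order (stable sort), so the
#' assignment is invariant to permuting the input rows.
#'
#' @param z Allele score vector (no missing values).
#' @param x Exposure vector (no missing values).
#' @param k Number of strata (default 100).
#' @return An integer vector of stratum indices in `1..k`, `NA` for dropped
#'   remainder rows, with attribute `dropped` (count).
#' @examples
#' doubly_ranked_strata(z = 1:9, x = c(1, 2, 3, 1, 2, 3, 1, 2, 3), k = 3)
#' @export
doubly_ranked_strata <- function(z, x, k = 100) {
  n <- length(z)
  stopifnot(length(x) == n)
  if (anyNA(z) || anyNA(x)) abort("z and x must have no missing values")
  k <- as.integer(k)
  if (n < k) {
    abort(paste0("infeasible stratification: N = ", n, " < K = ", k),
          class = "vitdmr_infeasible_stratification")
  }
  ord <- order(z)                     # stable: ties keep original row order
  q <- n %/% k
  dropped <- n - q * k
  assign <- rep(NA_integer_, n)
  for (b in seq_len(q)) {
    idx <- ord[((b - 1L) * k + 1L):(b * k)]
    assign[idx[order(x[idx])]] <- seq_len(k)
  }
  if (dropped > 0) {
    inform(paste0("doubly_ranked_strata: dropped ", dropped,
                  " individual(s) from the incomplete final pre-stratum"))
  }
  attr(assign, "dropped") <- dropped
  assign
}

#' Localized average causal effects per stratum
#'
#' Within each stratum the LACE is the ratio of the covariate-adjusted
#' score-outcome coefficient (estimated in the stratum) to the score-exposure
#' coefficient estimated once in the whole analysed sample, with
#' `lace_se = se_zy / |beta_zx|` (delta method; the population denominator is
#' treated as fixed, which is accurate for very strong instruments - a warning
#' is emitted when the population first-stage F is below 100). With
#' `denominator = "stratum"` the stratum-specific first-stage coefficient is
#' used instead, as in some published implementations.
#'
#' @param assignments Stratum assignment from [doubly_ranked_strata()].
#' @param z,x,y Score, exposure and outcome vectors.
#' @param covariates Optional adjustment columns (applied to both regressions).
#' @param min_stratum_n Smallest stratum size allowed for the adjusted
#'   regression (default 30); smaller strata raise an error advising fewer
#'   strata.
#' @param denominator `"population"` (default) or `"stratum"`.
#' @return A tibble of class `stratum_estimates`: `stratum`, `n`, `mean_x`,
#'   `beta_zy`, `se_zy`, `lace`, `lace_se`; population `beta_zx` and first
#'   stage F are stored as attributes.
#' @export
lace_per_stratum <- function(assignments, z, x, y, covariates = NULL,
                             min_stratum_n = 30,
                             denominator = c("population", "stratum")) {
  denominator <- match.arg(denominator)
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n, length(assignments) == n)
  keep <- !is.na(assignments)
  Xcov <- covariate_matrix(covariates)
  if (!is.null(Xcov)) stopifnot(nrow(Xcov) == n)

  fs <- first_stage(z[keep], x[keep],
                    if (is.null(Xcov)) NULL else Xcov[keep, , drop = FALSE])
  if (fs$f < 100) {
    warn(sprintf(paste0("population first-stage F = %.1f (< 100): treating the ",
                        "LACE denominator as fixed may understate lace_se"),
                 fs$f))
  }

  strata_ids <- sort(unique(assignments[keep]))
  rows <- lapply(strata_ids, function(j) {
    idx <- which(!is.na(assignments) & assignments == j)
    nj <- length(idx)
    if (nj < min_stratum_n) {
      abort(paste0("stratum ", j, " has n = ", nj, " (< ", min_stratum_n,
                   "): too small for the covariate-adjusted regression; ",
                   "use fewer strata (smaller K)"),
            class = "vitdmr_stratum_too_small")
    }
    Xj <- cbind(`(Intercept)` = rep(1, nj), z = z[idx])
    if (!is.null(Xcov)) {
      Xj <- drop_aliased_cols(
        cbind(Xj, drop_constant_cols(Xcov[idx, , drop = FALSE]))
      )
      if (!"z" %in% colnames(Xj)) {
        abort(paste0("degenerate instrument in stratum ", j,
                     ": score is collinear with the covariates"),
              class = "vitdmr_degenerate_instrument")
      }
    }
    fit <- ols_fit(Xj, y[idx])
    V <- ols_vcov(fit)
    beta_zy <- unname(fit$coef["z"])
    se_zy <- sqrt(V["z", "z"])
    den <- if (denominator == "population") fs$beta_zx else {
      first_stage(z[idx], x[idx],
                  if (is.null(Xcov)) NULL else
                    drop_constant_cols(Xcov[idx, , drop = FALSE]))$beta_zx
    }
    tibble::tibble(
      stratum = j, n = nj, mean_x = mean(x[idx]),
      beta_zy = beta_zy, se_zy = se_zy,
      lace = beta_zy / den, lace_se = se_zy / abs(den)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "beta_zx") <- fs$beta_zx
  attr(out, "f_statistic") <- fs$f
  attr(out, "denominator") <- denominator
  class(out) <- c("stratum_estimates", class(out))
  out
}

# Derivative of the FP basis: the meta-regression models the LACE (the local
# slope h'(x)) as the derivative of a fractional polynomial h, so its design
# columns are d/dx of each h-basis term evaluated at the stratum mean
# exposures. Column names match fp_basis() so coefficients carry over to the
# antiderivative when the curve is integrated.
fp_deriv_basis <- function(x, powers) {
  check_positive_x(x)
  d_plain <- function(p) if (p == 0) 1 / x else p * x^(p - 1)
  if (length(powers) == 1) {
    m <- cbind(d_plain(powers))
    colnames(m) <- fp_term_name(powers)
  } else if (powers[1] == powers[2]) {
    p <- powers[1]
    second <- if (p == 0) 2 * log(x) / x else x^(p - 1) * (p * log(x) + 1)
    m <- cbind(d_plain(p), second)
    colnames(m) <- c(fp_term_name(p), fp_term_name(p, with_log = TRUE))
  } else {
    m <- cbind(d_plain(powers[1]), d_plain(powers[2]))
    colnames(m) <- c(fp_term_name(powers[1]), fp_term_name(powers[2]))
  }
  m
}

fit_lace_powers <- function(mean_x, lace, w, powers) {
  X <- fp_deriv_basis(mean_x, powers)
  fit <- wls_fit(X, lace, w)
  structure(
    list(
      label = if (identical(as.numeric(powers), 1)) "linear" else
        if (length(powers) == 1) "fp1" else "fp2",
      degree = length(powers),
      powers = as.numeric(powers),
      coefficients = fit$coef,
      vcov = fit$vcov,
      wdev = fit$wrss,
      n_strata = length(lace)
    ),
    class = "lace_fp"
  )
}

#' Fractional-polynomial meta-regression of LACE on stratum exposure
#'
#' Weighted least squares (weights `1/lace_se^2`, treated as known) of the
#' stratum LACE estimates on the derivative basis of each candidate
#' fractional polynomial for the causal function h: for degree 1, the single
#' model `h(x) = beta * x^p` (so `h'(x) = beta * p * x^(p-1)`, or `beta/x`
#' when p = 0) over the 8 powers; for degree 2, all 36 power pairs with
#' repetition. Note that power 1 gives `h'` constant - the linear causal
#' model - so the linear model is a member of the degree-1 family. The best
#' model minimizes the weighted deviance (weighted RSS); ties break toward
#' the earlier candidate.
#'
#' @param strata A `stratum_estimates` tibble from [lace_per_stratum()] (or
#'   any tibble with `mean_x`, `lace`, `lace_se`).
#' @param degree 1 or 2.
#' @return An object of class `lace_fp`: `powers`, `coefficients`, `vcov`
#'   (`(X'WX)^{-1}`), `wdev` (weighted deviance), `n_strata`.
#' @export
fp_meta_regression <- function(strata, degree = 1) {
  stopifnot(degree %in% 1:2)
  ok <- is.finite(strata$lace) & is.finite(strata$lace_se) & strata$lace_se > 0
  strata <- strata[ok, , drop = FALSE]
  if (nrow(strata) < 10) {
    abort("fp_meta_regression needs at least 10 strata with finite lace_se")
  }
  if (max(strata$mean_x) - min(strata$mean_x) < .Machine$double.eps^0.5) {
    abort("degenerate meta-regression design: all stratum mean exposures equal",
          class = "vitdmr_degenerate_meta_design")
  }
  w <- 1 / strata$lace_se^2
  S <- fp_powers()
  candidates <- if (degree == 1) as.list(S) else {
    out <- list()
    for (i in seq_along(S)) for (j in i:length(S)) {
      out[[length(out) + 1]] <- c(S[i], S[j])
    }
    out
  }
  best <- NULL
  for (pw in candidates) {
    fit <- fit_lace_powers(strata$mean_x, strata$lace, w, pw)
    if (is.null(best) || fit$wdev < best$wdev - 1e-10) best <- fit
  }
  best
}

#' Test for nonlinearity of the causal dose-response
#'
#' Compares the best-fitting degree-1 fractional polynomial for the causal
#' function against the linear causal model (constant LACE, i.e. power 1):
#' statistic = weighted deviance(linear) - weighted deviance(best FP1),
#' referred to chi-squared with 1 df.
#'
#' @param strata A `stratum_estimates` tibble.
#' @param best_fp1 The degree-1 [fp_meta_regression()] fit on the same strata.
#' @return An `lr_test` tibble (`statistic`, `df`, `p`).
#' @export
nonlinearity_test <- function(strata, best_fp1) {
  stopifnot(inherits(best_fp1, "lace_fp"))
  ok <- is.finite(strata$lace) & is.finite(strata$lace_se) & strata$lace_se > 0
  strata <- strata[ok, , drop = FALSE]
  if (nrow(strata) != best_fp1$n_strata) {
    abort("incomparable fits: strata differ from those used for `best_fp1`",
          class = "vitdmr_incomparable_fits")
  }
  w <- 1 / strata$lace_se^2
  lin <- fit_lace_powers(strata$mean_x, strata$lace, w, 1)
  lr_test(lin$wdev - best_fp1$wdev, df = 1)
}

#' Integrate the fitted LACE function to a causal curve
#'
#' The meta-regression models the local slope h'(x); its closed-form
#' antiderivative (term `x^p` integrating the derivative basis back to the
#' h basis, with `ln x` for p = 0 and `x` for the linear model) gives the
#' causal difference curve `h(x) - h(reference)`, anchored to 0 at the
#' reference with a zero-width interval there. Pointwise 95% CIs use the same
#' linear contrast on the WLS coefficient covariance.
#'
#' @param fit A `lace_fp` from [fp_meta_regression()].
#' @param reference Reference exposure (nmol/L), default 50.
#' @param grid Positive exposure grid.
#' @return A `causal_curve` tibble.
#' @export
integrate_curve <- function(fit, reference = 50, grid = seq(15, 90, by = 1)) {
  stopifnot(inherits(fit, "lace_fp"))
  contrast_curve(fit$powers, fit$coefficients, fit$vcov, reference, grid)
}

#' Nonlinear Mendelian randomization on a cohort table
#'
#' The full pipeline: derive the weighted allele score (if absent), stratify
#' by the doubly-ranked method, estimate the LACE in each stratum (adjusted
#' for month of blood draw, supplementation and 10 genetic principal
#' components), fit the degree-1 fractional-polynomial meta-regression, test
#' for nonlinearity against the linear causal model, and integrate the fitted
#' slope function to a reference-anchored causal curve. The linear MR
#' estimate ([linear_mr()]) is always computed as the fallback reported when
#' nonlinearity is not supported.
#'
#' @param cohort A cohort tibble.
#' @param sex `"male"`, `"female"`, or `NULL` for all rows.
#' @param instrument [instrument_spec()] used when `score` is not a column.
#' @param k Number of strata (default 100).
#' @param reference Reference exposure in nmol/L (default 50).
#' @param grid Exposure grid for the curve.
#' @param alpha Significance level for the nonlinearity test.
#' @param min_stratum_n Passed to [lace_per_stratum()].
#' @param denominator Passed to [lace_per_stratum()].
#' @return A list of class `nlmr_result`: `strata`, `fit` (the `lace_fp`),
#'   `p_nonlinear`, `test_nonlinear`, `curve`, `linear` (the `mr_result`
#'   fallback), `selected` (`"nonlinear"` or `"linear"`), `k`, `n`, `dropped`.
#' @export
run_nonlinear_mr <- function(cohort, sex = NULL, instrument = NULL, k = 100,
                             reference = 50, grid = seq(15, 90, by = 1),
                             alpha = 0.05, min_stratum_n = 30,
                             denominator = c("population", "stratum")) {
  denominator <- match.arg(denominator)
  data <- filter_sex(cohort, sex)
  check_columns(data, c("vitd", "grip"))
  z <- cohort_score(data, instrument)
  covs <- mr_covariates(data)
  assign <- doubly_ranked_strata(z, data$vitd, k = k)
  strata <- lace_per_stratum(assign, z, data$vitd, data$grip, covs,
                             min_stratum_n = min_stratum_n,
                             denominator = denominator)
  fit <- fp_meta_regression(strata, degree = 1)
  test <- nonlinearity_test(strata, fit)
  curve <- integrate_curve(fit, reference = reference, grid = grid)
  lin <- linear_mr(z, data$vitd, data$grip, covs)
  structure(
    list(
      sex = sex, n = length(z), k = k,
      dropped = attr(assign, "dropped"),
      strata = strata,
      fit = fit,
      test_nonlinear = test,
      p_nonlinear = test$p,
      curve = curve,
      linear = lin,
      reference = reference,
      selected = if (test$p < alpha) "nonlinear" else "linear"
    ),
    class = "nlmr_result"
  )
}

#' @export
print.lace_fp <- function(x, ...) {
  cat("<lace_fp> ", x$label, " meta-regression of LACE, powers (",
      paste(x$powers, collapse = ", "), ")\n", sep = "")
  cat("  strata =", x$n_strata, ", weighted deviance =",
      format(x$wdev, digits = 6), "\n")
  invisible(x)
}

#' @export
print.nlmr_result <- function(x, ...) {
  cat("<nlmr_result> nonlinear MR, doubly-ranked method",
      paste0("(K = ", x$k, ", n = ", x$n, ")\n"))
  cat("  fitted causal FP1 powers (", paste(x$fit$powers, collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  p_nonlinear = %.4g -> %s model reported\n",
              x$p_nonlinear, x$selected))
  cat(sprintf("  linear MR fallback: %.3f kg (95%% CI %.3f, %.3f) per 25 nmol/L\n",
              x$linear$beta_per_25, x$linear$ci95[1], x$linear$ci95[2]))
  invisible(x)
}

#' @export
tidy.nlmr_result <- function(x, ...) tibble::as_tibble(x$strata)

#' @export
glance.nlmr_result <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = x$n,
    powers = paste(x$fit$powers, collapse = ","),
    p_nonlinear = x$p_nonlinear,
    selected = x$selected,
    linear_beta_per_25 = x$linear$beta_per_25,
    first_stage_f = x$linear$f_statistic
  )
}
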