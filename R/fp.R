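#' The fractional-polynomial power set
#'
#' The canonical 8-element power set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where
#' a power of 0 denotes the natural logarithm.
#'
#' @return Numeric vector of length 8.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_term_name <- function(p, with_log = FALSE) {
  base <- if (p == 0) "ln(x)" else sprintf("x^%g", p)
  if (with_log) paste0(base, "*ln(x)") else base
}

#' Fractional-polynomial basis
#'
#' Builds the design columns for powers drawn from [fp_powers()]: power `p`
#' maps to `x^p`, `p = 0` to `ln(x)`, and a repeated power `(p, p)` to the
#' pair `x^p` and `x^p * ln(x)` (for `p = 0`: `ln(x)` and `ln(x)^2`),
#' following the Royston-Altman convention.
#'
#' @param x Positive exposure values.
#' @param powers Numeric vector of length 1 or 2.
#' @return A numeric matrix with one column per basis term.
#' @examples
#' fp_basis(c(2, 4), c(0.5, 0.5))
#' @export
fp_basis <- function(x, powers) {
  check_positive_x(x)
  stopifnot(length(powers) %in% 1:2)
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) {
    m <- cbind(one(powers))
    colnames(m) <- fp_term_name(powers)
  } else if (powers[1] == powers[2]) {
    m <- cbind(one(powers[1]), one(powers[1]) * log(x))
    colnames(m) <- c(fp_term_name(powers[1]),
                     fp_term_name(powers[1], with_log = TRUE))
  } else {
    m <- cbind(one(powers[1]), one(powers[2]))
    colnames(m) <- c(fp_term_name(powers[1]), fp_term_name(powers[2]))
  }
  m
}

check_positive_x <- function(x) {
  bad <- sum(!is.finite(x) | x <= 0)
  if (bad > 0) {
    abort(paste0("domain error: ", bad,
                 " exposure value(s) are nonpositive or nonfinite; ",
                 "fractional-polynomial powers require x > 0"),
          class = "vitdmr_domain_error")
  }
  invisible(x)
}

fp_complexity <- function(label) {
  switch(label, linear = 1L, fp1 = 2L, fp2 = 4L,
         abort("unknown model label"))
}

new_fp_fit <- function(fit, powers, label, fp_names, n, xrange) {
  structure(
    list(
      label = label,
      degree = if (label == "linear") 1L else length(powers),
      powers = powers,
      coefficients = fit$coef,
      vcov = ols_vcov(fit),
      deviance = fit$deviance,
      rss = fit$rss,
      n = n,
      fp_terms = fp_names,
      complexity = fp_complexity(label),
      xrange = xrange
    ),
    class = "fp_fit"
  )
}

fit_one_fp <- function(y, Xcov, x, powers, label) {
  B <- fp_basis(x, powers)
  X <- cbind(`(Intercept)` = 1, B, Xcov)
  fit <- ols_fit(X, y)
  new_fp_fit(fit, powers, label, colnames(B), length(y), range(x))
}

#' Fit a fractional-polynomial regression by exhaustive power search
#'
#' Ordinary least squares of `y` on an FP basis in `x` plus covariates, with
#' the powers chosen by exhaustive search: all 8 FP1 models, or all 36 FP2
#' power pairs with repetition. The best model minimizes the Gaussian
#' deviance (-2 log-likelihood); ties break toward the earlier candidate in
#' enumeration order (increasing powers).
#'
#' @param y Outcome vector (grip strength, kg).
#' @param x Positive exposure vector (25(OH)D, nmol/L), modelled in native
#'   units without pre-scaling.
#' @param covariates Optional data frame or numeric matrix of adjustment
#'   columns (factors are expanded to dummies).
#' @param degree 1 or 2.
#' @return An object of class `fp_fit`: selected `powers`, `coefficients`,
#'   coefficient covariance `vcov`, Gaussian `deviance`, and bookkeeping used
#'   by [compare_fp()] and [curve_from_fp()].
#' @seealso [fit_fp_powers()] to fix the powers (including the plain linear
#'   model), [compare_fp()] for likelihood-ratio comparisons.
#' @examples
#' x <- runif(200, 20, 80)
#' y <- 3 * log(x) + rnorm(200, 0, 0.1)
#' fit <- fit_fp(y, x, degree = 1)
#' fit$powers
#' @export
fit_fp <- function(y, x, covariates = NULL, degree = 1) {
  stopifnot(degree %in% 1:2, length(y) == length(x))
  check_positive_x(x)
  Xcov <- covariate_matrix(covariates)
  if (!is.null(Xcov) && nrow(Xcov) != length(y)) {
    abort("covariates must have one row per observation")
  }
  S <- fp_powers()
  candidates <- if (degree == 1) {
    lapply(S, function(p) p)
  } else {
    out <- list()
    for (i in seq_along(S)) for (j in i:length(S)) {
      out[[length(out) + 1]] <- c(S[i], S[j])
    }
    out
  }
  best <- NULL
  label <- if (degree == 1) "fp1" else "fp2"
  for (pw in candidates) {
    fit <- fit_one_fp(y, Xcov, x, pw, label)
    if (is.null(best) || fit$deviance < best$deviance - 1e-10) best <- fit
  }
  best
}

#' @rdname fit_fp
#' @param powers Fixed powers to use instead of searching. `powers = 1` with
#'   `linear = TRUE` (the default for that case) labels the fit as the plain
#'   linear model for degrees-of-freedom accounting in [compare_fp()].
#' @param linear Logical; treat the fit as the linear reference model.
#' @export
fit_fp_powers <- function(y, x, covariates = NULL, powers, linear = identical(powers, 1)) {
  stopifnot(length(y) == length(x), length(powers) %in% 1:2)
  check_positive_x(x)
  Xcov <- covariate_matrix(covariates)
  label <- if (linear) {
    if (!identical(as.numeric(powers), 1)) {
      abort("the linear reference model must have powers = 1")
    }
    "linear"
  } else if (length(powers) == 1) "fp1" else "fp2"
  fit_one_fp(y, Xcov, x, powers, label)
}

#' Likelihood-ratio comparison of nested fractional-polynomial fits
#'
#' Compares two fits of the same data by the difference in Gaussian deviance,
#' referred to a chi-squared distribution with degrees of freedom following
#' the Royston convention: FP1 vs linear 1 df, FP2 vs FP1 2 df, FP2 vs linear
#' 3 df. A `p < .05` on the best FP versus linear is read as evidence of a
#' nonlinear association.
#'
#' @param fit_small,fit_big `fp_fit` objects for the simpler and richer model,
#'   fitted to the same observations.
#' @return A tibble of class `lr_test` with columns `statistic`, `df`, `p`.
#' @export
compare_fp <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "fp_fit"), inherits(fit_big, "fp_fit"))
  if (fit_small$n != fit_big$n) {
    abort("incomparable fits: models were fitted to different numbers of rows",
          class = "vitdmr_incomparable_fits")
  }
  if (fit_big$complexity < fit_small$complexity) {
    abort("incomparable fits: `fit_big` is not the richer model",
          class = "vitdmr_incomparable_fits")
  }
  df <- max(fit_big$complexity - fit_small$complexity, 1L)
  statistic <- max(fit_small$deviance - fit_big$deviance, 0)
  lr_test(statistic, df)
}

lr_test <- function(statistic, df) {
  out <- tibble::tibble(
    statistic = max(statistic, 0),
    df = as.integer(df),
    p = pchisq(max(statistic, 0), df = df, lower.tail = FALSE)
  )
  class(out) <- c("lr_test", class(out))
  out
}

# Reference-anchored difference curve from FP coefficients and their
# covariance block: diff(x) = B(x) b - B(ref) b with pointwise 95% CI from
# the linear contrast. Shared by the observational arm (OLS fit) and the
# nonlinear-MR integral (WLS meta-regression fit).
contrast_curve <- function(powers, beta, V, reference, grid) {
  check_positive_x(grid)
  check_positive_x(reference)
  B <- fp_basis(grid, powers)
  Bref <- fp_basis(reference, powers)
  C <- sweep(B, 2, as.numeric(Bref))
  est <- as.numeric(C %*% beta)
  se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  z <- qnorm(0.975)
  out <- tibble::tibble(
    x = as.numeric(grid),
    difference = est,
    se = se,
    lower95 = est - z * se,
    upper95 = est + z * se
  )
  attr(out, "reference") <- reference
  class(out) <- c("causal_curve", class(out))
  out
}

#' Reference-anchored mean-difference curve from a fitted FP model
#'
#' Evaluates the fitted mean difference in the outcome at each grid exposure
#' relative to the reference (default 50 nmol/L), using the FP coefficients
#' only (covariates held fixed). The pointwise 95% CI comes from the linear
#' contrast `b(x) - b(ref)` applied to the FP block of the coefficient
#' covariance; by construction the curve is 0 at the reference with a
#' zero-width interval.
#'
#' @param fit An `fp_fit`.
#' @param reference Reference exposure in nmol/L.
#' @param grid Exposure grid (nmol/L, positive). Values outside the fitted
#'   exposure range trigger a warning (extrapolation).
#' @return A `causal_curve` tibble: `x`, `difference`, `se`, `lower95`,
#'   `upper95`, with the reference stored as an attribute.
#' @export
curve_from_fp <- function(fit, reference = 50, grid = seq(15, 90, by = 1)) {
  stopifnot(inherits(fit, "fp_fit"))
  check_positive_x(grid)
  pts <- c(reference, grid)
  if (!is.null(fit$xrange) &&
      (min(pts) < fit$xrange[1] || max(pts) > fit$xrange[2])) {
    warn("curve evaluated outside the observed exposure range (extrapolation)")
  }
  idx <- fit$fp_terms
  contrast_curve(fit$powers, fit$coefficients[idx],
                 fit$vcov[idx, idx, drop = FALSE], reference, grid)
}

#' Export a difference curve as CSV
#'
#' @param curve A `causal_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_csv(curve[, c("x", "difference", "lower95", "upper95")], path)
  invisible(path)
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit> ", x$label,
      if (x$label != "linear") paste0(", powers (", paste(x$powers, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  n = ", x$n, ", deviance = ", format(x$deviance, digits = 8), "\n", sep = "")
  fp <- x$coefficients[x$fp_terms]
  cat("  FP terms: ",
      paste(sprintf("%s = %.5g", names(fp), fp), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fp_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(se),
    fp_term = names(x$coefficients) %in% x$fp_terms
  )
}

#' @export
glance.fp_fit <- function(x, ...) {
  tibble::tibble(
    model = x$label,
    powers = paste(x$powers, collapse = ","),
    deviance = x$deviance,
    n = x$n
  )
}
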