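# Internal least-squares helpers shared by the fractional-polynomial engine,
# the MR regressions and the LACE meta-regression. lm() is avoided in the hot
# paths (stratum loops, exhaustive power searches) where only coefficients,
# RSS and a covariance block are needed.

# Ordinary least squares on an explicit design matrix (intercept included by
# the caller). Returns Gaussian ML deviance (-2 log-likelihood).
ols_fit <- function(X, y, singular_ok = FALSE) {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X) && !singular_ok) {
    abort(paste0("singular fit: design matrix is rank deficient (rank ",
                 fit$rank, " < ", ncol(X), " columns)"),
          class = "vitdmr_singular_fit")
  }
  n <- length(y)
  rss <- sum(fit$residuals^2)
  list(
    coef = fit$coefficients,
    rss = rss,
    deviance = n * (log(2 * pi * rss / n) + 1),
    n = n,
    rank = fit$rank,
    df_residual = n - fit$rank,
    qr = fit$qr
  )
}

# (X'X)^{-1} * sigma2_hat in original column order (undoes LINPACK pivoting).
ols_vcov <- function(fit) {
  p <- length(fit$coef)
  R <- qr.R(fit$qr)
  Vp <- chol2inv(R)
  piv <- fit$qr$pivot
  V <- matrix(NA_real_, p, p)
  V[piv, piv] <- Vp
  V <- V * fit$rss / fit$df_residual
  dimnames(V) <- list(names(fit$coef), names(fit$coef))
  V
}

# Weighted least squares with fixed (known) weights, meta-analysis style:
# coefficient covariance is (X'WX)^{-1} with no residual dispersion factor,
# and the reported deviance is the weighted RSS (a chi-squared quantity when
# the weights are inverse variances).
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  fit <- lm.fit(Xw, y * sw)
  if (fit$rank < ncol(X)) {
    abort("singular fit: weighted design matrix is rank deficient",
          class = "vitdmr_singular_fit")
  }
  R <- qr.R(fit$qr)
  Vp <- chol2inv(R)
  piv <- fit$qr$pivot
  p <- ncol(X)
  V <- matrix(NA_real_, p, p)
  V[piv, piv] <- Vp
  dimnames(V) <- list(colnames(X), colnames(X))
  list(
    coef = setNames(fit$coefficients, colnames(X)),
    vcov = V,
    wrss = sum(fit$residuals^2),
    n = length(y)
  )
}

# Expand a covariate data frame (factors to dummies) without an intercept.
# Returns NULL for NULL/empty input so designs can be cbind()-ed directly.
covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    return(covariates)
  }
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) return(NULL)
  mm <- model.matrix(~., data = covariates)
  mm[, -1, drop = FALSE]
}

# Drop columns with no variation (arises when a factor level is absent from
# a stratum after subsetting a global design matrix).
drop_constant_cols <- function(X) {
  keep <- apply(X, 2, function(col) max(col) > min(col))
  X[, keep, drop = FALSE]
}

# Reduce a design matrix to a linearly independent column set (QR pivoting).
# Subsetting a global dummy matrix to a stratum can alias the intercept with
# a dummy block when the reference level is absent there.
drop_aliased_cols <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return(X)
  X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
}

check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1 || !sex %in% c("male", "female")) {
    abort('`sex` must be "male" or "female"')
  }
  sex
}

filter_sex <- function(cohort, sex) {
  if (is.null(sex)) return(cohort)
  check_sex(sex)
  dplyr::filter(cohort, .data$sex == !!sex)
}

# Covariate set for the observational arm: determinants of 25(OH)D
# (month of blood draw as a 12-level factor, supplementation) plus potential
# confounders (age, smoking, BMI, Townsend deprivation).
observational_covariates <- function(cohort) {
  need <- c("month_of_draw", "supplement", "age", "smoking", "bmi", "townsend")
  check_columns(cohort, need)
  data.frame(
    month = factor(cohort$month_of_draw, levels = 1:12),
    supplement = as.numeric(cohort$supplement),
    age = as.numeric(cohort$age),
    smoking = factor(cohort$smoking, levels = c("never", "previous", "current")),
    bmi = as.numeric(cohort$bmi),
    townsend = as.numeric(cohort$townsend)
  )
}

# Covariate set for the MR regressions: determinants of 25(OH)D and genetic
# ancestry (10 principal components); confounders are deliberately excluded
# (the instrument is assumed independent of them).
mr_covariates <- function(cohort) {
  pcs <- paste0("pc", 1:10)
  need <- c("month_of_draw", "supplement", pcs)
  check_columns(cohort, need)
  out <- data.frame(
    month = factor(cohort$month_of_draw, levels = 1:12),
    supplement = as.numeric(cohort$supplement)
  )
  for (p in pcs) out[[p]] <- as.numeric(cohort[[p]])
  out
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_complete <- function(df, cols) {
  sub <- df[, intersect(cols, names(df)), drop = FALSE]
  ok <- complete.cases(sub)
  if (!all(ok)) {
    abort(paste0(sum(!ok), " row(s) have missing values in analysed columns; ",
                 "the analysis requires complete cases"))
  }
  invisible(df)
}
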