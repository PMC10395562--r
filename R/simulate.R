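#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults come
#' from the packaged `ukb_like` profile (`inst/extdata/ukb_like.yaml`), which
#' calibrates the exposure to mean 49.9 / SD 21.1 nmol/L, grip strength to
#' 41.9 (8.9) kg in males and 25.2 (6.3) kg in females, and the allele score
#' to 2.5% of exposure variance.
#'
#' @param n Number of participants (>= 1).
#' @param seed Integer RNG seed; identical `(config, seed)` gives a
#'   bit-identical cohort.
#' @param causal_fn True causal dose-response, see [causal_null()].
#' @param sex_fraction_male Proportion of males.
#' @param target_score_r2 Proportion of exposure variance (natural scale)
#'   explained by the weighted allele score, in `[0, 1)`.
#' @param exposure_mean,exposure_sd Calibration targets for 25(OH)D (nmol/L).
#' @param outcome_mean_male,outcome_sd_male,outcome_mean_female,outcome_sd_female
#'   Calibration targets for grip strength (kg).
#' @param season_amplitude Peak-to-mean seasonal swing in 25(OH)D (nmol/L at
#'   the exposure mean); a sinusoid peaking in July.
#' @param supplement_prevalence,supplement_effect Proportion supplementing and
#'   the 25(OH)D increment (nmol/L at the exposure mean) among supplementers.
#' @param confounder_effects Named list (`age`, `bmi`, `townsend`,
#'   `smoking_previous`, `smoking_current`), each a list/vector with elements
#'   `x` (effect on log 25(OH)D per unit) and `y` (effect on grip in kg per
#'   unit). Set all to zero to switch confounding off.
#' @param age_effect_ratio Multiplier applied to the causal effect per age
#'   band (bands as in [age_band()]); 1 means an age-constant effect, 0.5
#'   halves the slope in each successive band (used to plant an
#'   age-interaction signal).
#' @param pleiotropy_bmi Direct effect of the standardized score on BMI
#'   (kg/m^2 per SD of score); nonzero values plant a pleiotropic path used
#'   by instrument-validation tests. Default 0.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n,
                       seed,
                       causal_fn = causal_null(),
                       sex_fraction_male = NULL,
                       target_score_r2 = NULL,
                       exposure_mean = NULL,
                       exposure_sd = NULL,
                       outcome_mean_male = NULL,
                       outcome_sd_male = NULL,
                       outcome_mean_female = NULL,
                       outcome_sd_female = NULL,
                       season_amplitude = NULL,
                       supplement_prevalence = NULL,
                       supplement_effect = NULL,
                       confounder_effects = NULL,
                       age_effect_ratio = 1,
                       pleiotropy_bmi = 0) {
  defaults <- ukb_like_profile()
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed), causal_fn = causal_fn,
    sex_fraction_male = sex_fraction_male %||% defaults$sex_fraction_male,
    target_score_r2 = target_score_r2 %||% defaults$target_score_r2,
    exposure_mean = exposure_mean %||% defaults$exposure_mean,
    exposure_sd = exposure_sd %||% defaults$exposure_sd,
    outcome_mean_male = outcome_mean_male %||% defaults$outcome_mean_male,
    outcome_sd_male = outcome_sd_male %||% defaults$outcome_sd_male,
    outcome_mean_female = outcome_mean_female %||% defaults$outcome_mean_female,
    outcome_sd_female = outcome_sd_female %||% defaults$outcome_sd_female,
    season_amplitude = season_amplitude %||% defaults$season_amplitude,
    supplement_prevalence = supplement_prevalence %||% defaults$supplement_prevalence,
    supplement_effect = supplement_effect %||% defaults$supplement_effect,
    confounder_effects = confounder_effects %||% defaults$confounder_effects,
    age_effect_ratio = age_effect_ratio,
    pleiotropy_bmi = pleiotropy_bmi
  )
  validate_sim_config(cfg)
}

ukb_like_profile <- function() {
  yaml::read_yaml(system.file("extdata", "ukb_like.yaml",
                              package = "vitdmr", mustWork = TRUE))
}

#' Zeroed confounder effects
#'
#' Convenience for simulations with confounding switched off.
#' @return A `confounder_effects` list with all path coefficients 0.
#' @export
no_confounding <- function() {
  eff <- ukb_like_profile()$confounder_effects
  lapply(eff, function(e) list(x = 0, y = 0))
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n) || cfg$n < 1) abort("configuration error: n must be >= 1")
  if (is.na(cfg$seed)) abort("configuration error: seed must be an integer")
  if (!inherits(cfg$causal_fn, "causal_fn")) {
    abort("configuration error: causal_fn must be a causal_fn object")
  }
  if (cfg$exposure_sd <= 0) abort("configuration error: exposure_sd must be > 0")
  if (cfg$target_score_r2 < 0 || cfg$target_score_r2 >= 1) {
    abort("configuration error: target_score_r2 must lie in [0, 1)")
  }
  if (cfg$supplement_prevalence < 0 || cfg$supplement_prevalence > 1) {
    abort("configuration error: supplement_prevalence must lie in [0, 1]")
  }
  if (cfg$sex_fraction_male < 0 || cfg$sex_fraction_male > 1) {
    abort("configuration error: sex_fraction_male must lie in [0, 1]")
  }
  need <- c("age", "bmi", "townsend", "smoking_previous", "smoking_current")
  missing <- setdiff(need, names(cfg$confounder_effects))
  if (length(missing)) {
    abort(paste0("configuration error: confounder_effects missing ",
                 paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "sim_config")
}

conf_effect <- function(cfg, name, axis) {
  as.numeric(cfg$confounder_effects[[name]][[axis]])
}

#' Simulate a UK-Biobank-like cohort
#'
#' Generates a complete-case participant table with the statistical structure
#' the downstream analyses assume: unlinked genotypes and a weighted allele
#' score; 25(OH)D generated on the natural-log scale (so the score acts
#' multiplicatively and the exposure stays positive) from the score, a
#' seasonal sinusoid peaking in July, supplementation, and confounders, then
#' standardized to hit the lognormal mean/SD targets and floored at the
#' 10 nmol/L assay limit; grip strength from the configured causal function
#' plus confounder paths and sex-specific intercept/noise calibrated to the
#' outcome mean/SD targets.
#'
#' The score coefficient is set analytically so that the realized variance in
#' 25(OH)D explained by the score (natural scale) matches
#' `target_score_r2`: the target is mapped to a log-scale variance share
#' through the lognormal attenuation factor
#' \eqn{\sigma_L / \sqrt{e^{\sigma_L^2} - 1}}.
#'
#' @param config A [sim_config()].
#' @param instrument An [instrument_spec()]; defaults to the packaged 6-SNP
#'   instrument.
#' @return A tibble with one row per participant: `id`, `sex`, `age`,
#'   `month_of_draw`, `supplement`, `smoking`, `bmi`, `townsend`,
#'   `pc1`..`pc10`, one dosage column per SNP, `score`, `vitd` (nmol/L) and
#'   `grip` (kg).
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 500, seed = 1))
#' dplyr::glimpse(cohort[, c("sex", "age", "vitd", "grip")])
#' @export
simulate_cohort <- function(config, instrument = default_instrument()) {
  cfg <- validate_sim_config(config)
  instrument <- validate_instrument(tibble::as_tibble(instrument))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg, instrument))
}

simulate_cohort_impl <- function(cfg, instrument) {
  n <- cfg$n

  sex <- ifelse(runif(n) < cfg$sex_fraction_male, "male", "female")
  age <- sample(40:73, n, replace = TRUE)
  month <- sample(1:12, n, replace = TRUE)
  supplement <- as.integer(runif(n) < cfg$supplement_prevalence)
  smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                    prob = c(0.55, 0.355, 0.095))
  bmi <- pmax(rnorm(n, 27.4, 4.7), 15)
  townsend <- rnorm(n, -1.56, 2.93)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  genotypes <- simulate_genotypes(n, instrument, seed = NULL)
  score <- weighted_score(genotypes, instrument)
  score_sd <- if (n > 1) sd(score) else 0
  z_std <- if (score_sd > 0) (score - mean(score)) / score_sd else rep(0, n)

  if (cfg$pleiotropy_bmi != 0) bmi <- bmi + cfg$pleiotropy_bmi * z_std

  smk_prev <- as.numeric(smoking == "previous")
  smk_curr <- as.numeric(smoking == "current")

  ## --- exposure on the log scale -------------------------------------------
  season <- (cfg$season_amplitude / cfg$exposure_mean) *
    cos(2 * pi * (month - 7) / 12)
  supp_term <- (cfg$supplement_effect / cfg$exposure_mean) * supplement
  conf_x <- conf_effect(cfg, "age", "x") * age +
    conf_effect(cfg, "bmi", "x") * bmi +
    conf_effect(cfg, "townsend", "x") * townsend +
    conf_effect(cfg, "smoking_previous", "x") * smk_prev +
    conf_effect(cfg, "smoking_current", "x") * smk_curr
  noise_x <- rnorm(n, 0, 0.38)
  g <- season + supp_term + conf_x + noise_x

  cv2 <- (cfg$exposure_sd / cfg$exposure_mean)^2
  sigma_l2 <- log(1 + cv2)
  sigma_l <- sqrt(sigma_l2)
  mu_l <- log(cfg$exposure_mean) - sigma_l2 / 2
  attenuation <- sigma_l / sqrt(exp(sigma_l2) - 1)
  r2_log <- cfg$target_score_r2 / attenuation^2
  if (r2_log >= 0.95) {
    abort("configuration error: target_score_r2 unattainable given the noise structure")
  }
  var_g <- if (n > 1) var(g) else 1
  b_score <- if (cfg$target_score_r2 > 0 && score_sd > 0) {
    sqrt(r2_log * var_g / (1 - r2_log))
  } else 0
  u <- b_score * z_std + g
  u_sd <- if (n > 1) sd(u) else 1
  u_std <- if (u_sd > 0) (u - mean(u)) / u_sd else rep(0, n)
  vitd <- pmax(exp(mu_l + sigma_l * u_std), 10)

  ## --- outcome --------------------------------------------------------------
  causal <- causal_effect(cfg$causal_fn, vitd)
  if (cfg$age_effect_ratio != 1) {
    band <- as.integer(age_band(age))
    causal <- causal * cfg$age_effect_ratio^(band - 1)
  }
  conf_y <- conf_effect(cfg, "age", "y") * age +
    conf_effect(cfg, "bmi", "y") * bmi +
    conf_effect(cfg, "townsend", "y") * townsend +
    conf_effect(cfg, "smoking_previous", "y") * smk_prev +
    conf_effect(cfg, "smoking_current", "y") * smk_curr
  m <- causal + conf_y

  grip <- numeric(n)
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    mu_t <- if (s == "male") cfg$outcome_mean_male else cfg$outcome_mean_female
    sd_t <- if (s == "male") cfg$outcome_sd_male else cfg$outcome_sd_female
    var_m <- if (length(idx) > 1) var(m[idx]) else 0
    noise_var <- sd_t^2 - var_m
    if (noise_var <= 0) {
      abort(paste0("configuration error: structural variance in the outcome (",
                   signif(var_m, 3), " kg^2) exceeds the ", s,
                   " target SD^2; increase outcome_sd or weaken effects"))
    }
    grip[idx] <- mu_t - mean(m[idx]) + m[idx] +
      rnorm(length(idx), 0, sqrt(noise_var))
  }
  grip <- pmax(grip, 1)  # grip strength is recorded only when > 0

  dplyr::bind_cols(
    tibble::tibble(
      id = seq_len(n), sex = sex, age = age, month_of_draw = month,
      supplement = supplement, smoking = smoking, bmi = bmi,
      townsend = townsend
    ),
    tibble::as_tibble(pcs),
    genotypes,
    tibble::tibble(score = score, vitd = vitd, grip = grip)
  )
}

#' Read or write a cohort table
#'
#' Tab-delimited text with one row per participant and the column layout
#' produced by [simulate_cohort()].
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
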