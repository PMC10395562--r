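# Independent oracles used across test files.

# Brute-force sort-and-deal stratification: explicit loops, ranks computed
# one pre-stratum at a time by repeatedly extracting the minimum-exposure
# member. Ties in score and exposure broken by the documented rule
# (original row order after the stable score sort).
oracle_strata <- function(z, x, k) {
  n <- length(z)
  res <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  # stable selection sort by z
  z_sorted <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[which.min(z[remaining])]  # which.min takes first on ties
    z_sorted <- c(z_sorted, i)
    remaining <- setdiff(remaining, i)
  }
  q <- floor(n / k)
  for (b in seq_len(q)) {
    members <- z_sorted[((b - 1) * k + 1):(b * k)]
    for (j in seq_len(k)) {
      pick <- members[which.min(x[members])]
      res[pick] <- j
      members <- setdiff(members, pick)
    }
  }
  res
}

# Two-stage least squares with a single instrument via explicit stage-wise
# lm() fits; the identity test uses the covariate-free form.
tsls_beta <- function(z, x, y) {
  xhat <- stats::fitted(stats::lm(x ~ z))
  unname(stats::coef(stats::lm(y ~ xhat))["xhat"])
}

# Small male-only cohort generator shared across tests.
male_cohort <- function(n, seed, causal_fn = causal_null(), ...) {
  simulate_cohort(sim_config(n = n, seed = seed, causal_fn = causal_fn,
                             sex_fraction_male = 1, ...))
}
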