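# vitdmr

Linear and nonlinear dose–response analysis of circulating
25-hydroxyvitamin D (25(OH)D, nmol/L) and maximum grip strength (kg),
combining a cross-sectional observational arm with Mendelian randomization
(MR) — for epidemiologists asking not just *whether* vitamin D status
affects muscle strength but *at which exposure levels*, since that is what
decides who could benefit from supplementation.

Because the individual-level biobank data such analyses use are restricted,
the package ships a calibrated synthetic cohort generator with the same
statistical structure (allele score instrument, seasonal and
supplementation structure in the exposure, sex-specific outcome
distributions, genuine confounding), so the entire pipeline is reproducible
and testable end to end.

## What it computes

* **Observational arm** — sex-stratified fractional-polynomial (FP)
  regression of grip on 25(OH)D, adjusted for month of blood draw,
  supplementation, age, smoking, BMI and Townsend deprivation. Powers are
  chosen from the Royston–Altman set S = {−2, −1, −0.5, 0, 0.5, 1, 2, 3}
  (0 ≡ ln x) by exhaustive deviance search; likelihood-ratio tests compare
  FP2 vs FP1 (2 df) and the best FP vs linear (`p_nonlinear`). Curves report
  f(x) − f(50) with pointwise 95% CIs. An age-stratified analysis refits the
  selected form in bands <50 / 50–59 / 60–64 / 65+ and tests age × exposure
  interaction.
* **Linear MR** — a weighted allele score Z = Σ wⱼgⱼ / Σ wⱼ (GWAS weights on
  the log-exposure scale) instruments 25(OH)D; the Wald ratio
  β̂_ZY / β̂_ZX (≡ 2SLS for a single instrument), adjusted for month,
  supplementation and 10 genetic principal components, is reported per
  25 nmol/L with first-stage R² and F diagnostics, plus a
  confounder-association scan of the instrument.
* **Nonlinear MR** — doubly-ranked stratification into K = 100 strata
  (rank by score into pre-strata, deal by exposure rank within
  pre-stratum); per-stratum localized average causal effects
  LACE_j = β̂_ZY,j / β̂_ZX; weighted FP meta-regression of LACE on stratum
  mean exposure modelling the derivative h′(x) of the causal function; a
  1-df FP1-vs-linear nonlinearity test; and the closed-form integral
  h(x) − h(50) as the causal curve.

## Worked example

Simulate a cohort whose true causal function is a plateau (0.04 kg per
nmol/L below a 50 nmol/L knot, flat above — about a 1 kg deficit at 25 vs
50 nmol/L), then run both arms; n = 50,000 keeps it at a few seconds:

```r
library(vitdmr)

cohort <- simulate_cohort(
  sim_config(n = 50000, seed = 42, causal_fn = causal_plateau(0.04, knot = 50))
)

obs <- run_observational(cohort, sex = "male", reference = 50)
obs
#> <obs_result> observational dose-response, male (n = 23261)
#>   selected model: fp2 with powers (-2, -2)
#>   p_nonlinear = 0.004441 (LR statistic 13.092 on 3 df)
obs$curve[obs$curve$x %in% c(25, 50, 75), ]
#> # A tibble: 3 x 5
#>       x difference     se lower95 upper95
#>   <dbl>      <dbl>  <dbl>   <dbl>   <dbl>
#> 1    25     -0.849 0.131   -1.11   -0.592
#> 2    50      0     0        0       0
#> 3    75      0.375 0.0560   0.265   0.484

run_nonlinear_mr(cohort, sex = "male", k = 50)
#> <nlmr_result> nonlinear MR, doubly-ranked method (K = 50, n = 23261)
#>   fitted causal FP1 powers (2)
#>   p_nonlinear = 0.3666 -> linear model reported
#>   linear MR fallback: 1.089 kg (95% CI 0.167, 2.011) per 25 nmol/L
```

Reading the output: the observational arm detects the curvature
(`p_nonlinear = .004`) and recovers the plateau's ~1 kg deficit at
25 nmol/L (−0.85 kg, 95% CI −1.11 to −0.59). The MR arm's nonlinearity test
does not reject at this sample size — stratum-level IV estimates are far
noisier than a covariate-adjusted regression — so the linear MR estimate is
reported: 1.09 kg per 25 nmol/L, the instrument-weighted average slope of
the plateau. `autoplot(obs$curve)` and `autoplot()` on the nonlinear-MR
result draw the curve and the stratum LACE estimates; `tidy()`/`glance()`
return tibble summaries; `confounder_scan(cohort)` checks the instrument
against age, BMI, deprivation and smoking.

The generator's defaults (`ukb_like` profile) calibrate 25(OH)D to mean
49.9 / SD 21.1 nmol/L with a 10 nmol/L assay floor, grip to 41.9 (8.9) kg in
males and 25.2 (6.3) kg in females, and the 6-SNP score to 2.5% of exposure
variance; `vignette("nonlinear-mr-methods")` documents every model,
parameter and design choice.

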