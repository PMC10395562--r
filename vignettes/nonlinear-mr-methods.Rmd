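---
title: "Methods: dose-response models and nonlinear Mendelian randomization in vitdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response models and nonlinear Mendelian randomization in vitdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

`vitdmr` studies how circulating 25-hydroxyvitamin D (25(OH)D, nmol/L)
relates to maximum grip strength (kg), the question asked of large biobank
cohorts where vitamin D status is both common and modifiable. Two arms are
triangulated: a cross-sectional observational analysis, which is precise but
vulnerable to confounding, and Mendelian randomization (MR), which uses a
weighted allele score as an instrument and is robust to classical confounding
but needs large samples. Both arms allow the dose-response to be nonlinear,
because the public-health question - who would benefit from supplementation -
hinges on the shape, not just the slope.

## Fractional polynomials

The functional form of the exposure is chosen from the Royston-Altman
fractional-polynomial (FP) family with the canonical power set
$S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, where power 0 denotes $\ln x$ and a
repeated pair $(p, p)$ contributes $x^p$ and $x^p \ln x$. Degree-1 models use
one power (8 candidates), degree-2 models a pair with repetition (36
candidates). Fits are ordinary least squares in native nmol/L units (no
pre-scaling or centering, so every curve is directly in nmol/L), and model
selection minimizes the Gaussian deviance ($-2$ log-likelihood), with ties
broken toward the earlier candidate in enumeration order (and hence toward
the simpler model).

Likelihood-ratio comparisons follow the usual df accounting for this family:
FP1 vs linear on 1 df, FP2 vs FP1 on 2 df, FP2 vs linear on 3 df. The
reported `p_nonlinear` compares the best-fitting FP against the linear
model; the selected FP1-vs-linear statistic is a maximum over the candidate
powers referred to $\chi^2_1$, so its finite-sample size is only
approximately nominal (slightly liberal in the observational arm,
mildly conservative in the meta-regression when the true constant effect is
small relative to its uncertainty) - a property of the convention itself,
visible in the type-I-error simulations in the test suite.

Reference-anchored curves report $f(x) - f(x_{ref})$ with $x_{ref} = 50$
nmol/L by default. Pointwise 95% intervals use the linear contrast
$b(x) - b(x_{ref})$ on the covariance of the FP coefficients only, holding
covariate coefficients fixed; any covariance between covariate and FP
coefficients is ignored, which we judge negligible for curve differences
(covariate terms cancel exactly in the contrast). At the reference the
difference is exactly 0 with a zero-width interval.

## Observational arm

Within each sex, grip strength is regressed on the FP basis of 25(OH)D,
adjusting for determinants of 25(OH)D (calendar month of blood draw as a
12-level factor, vitamin D supplementation) and potential confounders (age,
smoking status, BMI, Townsend deprivation). The age-stratified analysis
refits the pooled selected form in four fixed bands - `<50`, `50-59`,
`60-64`, `65+`, closed on the left - and tests age modification by comparing
the pooled model (plus band main effects) against the model adding band x
FP-term interactions ($3 \times$ number of FP terms df). Two deliberate
choices: the FP powers are *not* re-selected within bands (keeping the
interaction df interpretable), and age stays in the model as a continuous
covariate within bands (residual within-band age confounding is otherwise
possible at the band widths used).

## Linear MR

The instrument is the weighted average of 25(OH)D-increasing allele counts,
$Z_i = \sum_j w_j g_{ij} / \sum_j w_j$, with GWAS weights on the natural-log
exposure scale; any negatively weighted SNP is re-oriented at load
($g \to 2-g$). A weighted *average* (not sum) matches the construction we
emulate; MR estimates are invariant to that choice, though first-stage
coefficients are not. The causal estimate is the Wald ratio of the
covariate-adjusted (month, supplementation, 10 genetic principal components)
score-outcome and score-exposure coefficients, reported per 25 nmol/L. With
a single instrument the ratio and two-stage least squares coincide, so the
distinction between the two published phrasings is moot here. The standard
error is the first-order delta method with the denominator treated as fixed,
$|1/\hat\beta_{ZX}|\,se(\hat\beta_{ZY})$: at the instrument strengths this
method targets (first-stage F in the thousands) the neglected denominator
variance is negligible, and a warning is emitted whenever F < 10, where the
approximation is unsafe.

## Nonlinear MR

The doubly-ranked method stratifies on the instrument first: participants
are sorted by score into consecutive pre-strata of K members (K = 100 strata
by default); within each pre-stratum the individual with the j-th smallest
exposure goes to stratum j. Strata thus differ systematically in exposure
while keeping comparable score distributions. When K does not divide N the
incomplete final pre-stratum is dropped (and counted) - the simplest
defensible rule given N >> K in intended use. Ties in score or exposure are
broken by original row order after a stable sort, so assignments are
reproducible; with continuous data the assignment is also invariant to row
permutations.

Within stratum j the localized average causal effect (LACE) is
$\hat\beta_{ZY,j} / \hat\beta_{ZX}$, where the denominator is estimated once
in the whole analysed sample - exactly the construction we emulate - with
`denominator = "stratum"` available as a sensitivity switch. Its standard
error again treats the denominator as fixed (warning when the population
F < 100). Both regressions adjust for month, supplementation and 10 genetic
PCs. Strata smaller than 30 are refused with advice to lower K rather than
silently pooled: how sub-design-size strata should be handled is not
settled, and refusing is the conservative reading.

Because the LACE estimates the local slope $h'(x)$ of the causal function,
the meta-regression fits $h'$ by weighted least squares (weights
$1/se_j^2$, treated as known) of LACE on the *derivative* of each candidate
FP basis evaluated at the stratum mean exposure: degree 1 models
$h(x) = \beta x^p$, so $h'(x) = \beta p x^{p-1}$ ($\beta / x$ for $p = 0$).
Power 1 gives a constant $h'$ - the linear causal model - so the
nonlinearity test is the 1-df comparison of the best degree-1 model against
that member. (The construction we emulate is described as regressing mean
exposure "against" LACE; we take LACE as the response, which is the
established method, and read the wording as transposed.) Degree-2
meta-regression is implemented but the degree-1-vs-linear comparison is the
headline test. The causal curve is the closed-form antiderivative,
$h(x) - h(50)$, with CIs from the same contrast on the WLS covariance
$(X'WX)^{-1}$ (no residual dispersion factor, as in fixed-effect
meta-regression).

## The synthetic cohort generator

No individual-level biobank data can ship with a package, so every analysis
is exercised on `simulate_cohort()`, whose defaults (`ukb_like` profile) are
fixed study conditions, not tuning knobs:

* **Instrument**: 6 unlinked SNPs (dosages Binomial(2, freq), emulating an
  LD-clumped instrument), score calibrated to explain 2.5% of exposure
  variance - inside the 2.4-2.8% range reported for such scores.
* **Exposure**: generated on the log scale - the GWAS weights are log-scale,
  so the score acts multiplicatively and 25(OH)D stays positive - from the
  standardized score, a seasonal sinusoid peaking in July (amplitude 8
  nmol/L at the mean; the shape is our choice, only the need to adjust for
  month is given), supplementation (prevalence 7%, +10 nmol/L at the mean),
  and confounders; then standardized to lognormal parameters matching mean
  49.9 / SD 21.1 nmol/L and floored at the 10 nmol/L assay validity limit.
  The score coefficient is set analytically via the lognormal attenuation
  factor $\sigma_L / \sqrt{e^{\sigma_L^2} - 1}$ so the natural-scale
  variance explained hits its target without iteration. Exposure-side
  effects are specified relative to the exposure mean because of this final
  standardization.
* **Outcome**: grip = causal function of exposure + confounder paths +
  Gaussian noise, with sex-specific intercept and noise variance solved to
  match 41.9 (8.9) kg in males and 25.2 (6.3) kg in females; clamped at 1 kg
  (grip is recorded only when positive; the clamp probability is ~3e-5).
* **Confounders**: age, BMI, Townsend and smoking affect both exposure and
  outcome with fixed default path coefficients chosen so that, under a null
  causal function, the crude exposure-outcome slope is materially biased
  (several standard errors at n = 50,000+) while MR stays centred on the
  truth - the qualitative signature MR exists to exhibit. The magnitudes are
  generator choices; no empirical path coefficients were available to copy.
* **True causal functions**: null, linear, plateau and single-FP-term forms.
  The default plateau slope is 0.04 kg per nmol/L below a 50 nmol/L knot,
  sized to produce a realistic ~1 kg deficit at 25 vs 50 nmol/L.
  `age_effect_ratio` multiplies the causal term per age band to plant an
  age interaction; `pleiotropy_bmi` plants a direct score-to-BMI path for
  instrument-validation tests.

What the generator does **not** emulate: linkage disequilibrium between
variants, genotype file formats, missing data, selection/collider effects,
assortative mating, non-Gaussian outcome noise, or true effect heterogeneity
beyond the age-band multiplier. Passing tests therefore demonstrate the
statistical machinery under the assumed data-generating structure, not
robustness to those real-data complications.

## Numerical choices and problem sizes

Degenerate inputs error early and specifically: nonpositive exposures
(FP powers include logs and negative powers), rank-deficient designs,
constant instruments, strata below the size floor, fewer than 10 usable
strata in the meta-regression, all-equal stratum means. Within-stratum
designs built by subsetting a global dummy matrix drop aliased columns by QR
pivoting (a stratum can lose a factor's reference level). Deviance ties in
the FP search break toward the earlier, simpler candidate.

The test suite works at the scales the methods are designed for while
staying desk-sized: moment calibration at n = 100,000; parameter recovery
and shape recovery at n = 200,000 (male-only cohorts, so the analysed n
matches the stated size); type-I-error simulations with 200 replicates of
n = 20,000; power simulations with 50 replicates of n = 200,000. The
acceptance script analyses one mixed-sex cohort of n = 200,000 with a true
linear effect of 0.01 kg per nmol/L, i.e. 0.25 kg per 25 nmol/L - the
magnitude such cohorts are powered to detect.

## Known limitations

* The delta-method SEs ignore denominator uncertainty; downstream of a weak
  instrument they are anti-conservative (hence the F warnings).
* Curve CIs in the observational arm ignore covariate-FP coefficient
  covariance.
* The FP nonlinearity tests do not have exactly nominal size (see above);
  users needing exact size should calibrate by simulation for their design.
* The MR nonlinearity test has limited power at realistic effect sizes. At
  n = 200,000, K = 100, score R-squared 2.5% and outcome SD ~8.7 kg, the
  per-stratum LACE standard error is ~0.06 kg per nmol/L - larger than a
  realistic plateau slope of 0.04 - and the test's simulated power against
  that plateau is well under 50%. Two structural facts compound this: with a
  population-denominator LACE and a multiplicatively acting score, a plateau
  induces a *hump-shaped* LACE profile (rising proportionally to x below the
  knot, dropping to zero above), which the monotone single-term degree-1
  derivative bases cannot represent; the `denominator = "stratum"` switch
  restores the monotone step profile and substantially more power in the
  same simulations. A non-rejection therefore does not establish linearity,
  only that curvature of this magnitude is not detectable at this design -
  consistent with how such analyses read their null results.
* The doubly-ranked construction assumes the instrument is exchangeable
  across exposure levels; gross violations (e.g. strong gene-environment
  interaction) are outside the generator's scope and undetectable here.
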