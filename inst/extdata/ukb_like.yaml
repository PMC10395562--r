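# Default simulation profile: a UK-Biobank-like cohort.
# Exposure/outcome calibration targets are the published cohort summaries
# (25(OH)D mean 49.9, SD 21.1 nmol/L; grip 41.9 (8.9) kg males,
# 25.2 (6.3) kg females); the score variance target sits in the reported
# 2.4-2.8% range. Confounder path coefficients are generator choices
# (x-effects on the log-exposure scale per unit, y-effects in kg per unit).
sex_fraction_male: 0.467
exposure_mean: 49.9
exposure_sd: 21.1
outcome_mean_male: 41.9
outcome_sd_male: 8.9
outcome_mean_female: 25.2
outcome_sd_female: 6.3
target_score_r2: 0.025
season_amplitude: 8.0
supplement_prevalence: 0.07
supplement_effect: 10.0
confounder_effects:
  age: {"x": -0.002, "y": -0.20}
  bmi: {"x": -0.013, "y": -0.05}
  townsend: {"x": -0.010, "y": -0.12}
  smoking_previous: {"x": -0.03, "y": -0.30}
  smoking_current: {"x": -0.10, "y": -1.00}
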