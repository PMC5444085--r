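#!/usr/bin/env Rscript
# Estimates the field-surveyable behavioural indicators from the synthetic
# survey tables produced by 01_simulate_surveys.R.

suppressPackageStartupMessages({
  library(vectorcycle)
  library(jsonlite)
})
stopifnot(file.exists("results/biting_survey.csv"))

survey <- read_biting_survey("results/biting_survey.csv")
meals <- read_bloodmeals("results/bloodmeals.csv")
rest <- read_resting("results/resting.csv")

ed <- exposure_distribution(survey)
hbi <- human_blood_index(meals)
irf <- indoor_resting_fraction(rest["indoor"], rest["outdoor"])
rof <- residual_outdoor_fraction(survey, screening_efficacy = 0.9)

indicators <- list(
  pi_indoor = ed$pi_indoor,
  pi_in_bed = ed$pi_in_bed,
  residual_outdoor_under_screening = rof,
  q_human = hbi$estimate, q_human_lower = hbi$lower, q_human_upper = hbi$upper,
  f_livestock_meals = unname(meals[["cattle"]] / sum(meals)),
  indoor_resting = irf$estimate, indoor_resting_lower = irf$lower,
  indoor_resting_upper = irf$upper
)
write_json(indicators, "results/indicators.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)

cat(sprintf("indoor exposure fraction: %.3f (in bed: %.3f of indoor)\n",
            ed$pi_indoor, ed$pi_in_bed))
cat(sprintf("with 90%%-effective screening, %.1f%% of residual exposure is outdoors\n",
            100 * rof))
cat(sprintf("human blood index: %.3f [%.3f, %.3f]\n",
            hbi$estimate, hbi$lower, hbi$upper))
cat(sprintf("indoor-resting fraction: %.3f [%.3f, %.3f]\n",
            irf$estimate, irf$lower, irf$upper))
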