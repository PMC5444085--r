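#!/usr/bin/env Rscript
# Applies the opportunity-indicator thresholds to the estimated indicators
# and writes the per-technology recommendations.

suppressPackageStartupMessages({
  library(vectorcycle)
  library(jsonlite)
})
stopifnot(file.exists("results/indicators.json"))
ind <- read_json("results/indicators.json", simplifyVector = TRUE)

ip <- indicator_profile(
  pi_indoor_exposure = ind$pi_indoor,
  q_human = ind$q_human,
  f_livestock_meals = ind$f_livestock_meals,
  sleeps_indoors = TRUE,
  outdoor_night_activity = TRUE,
  owns_livestock = TRUE
)
recs <- recommend(ip)
write.csv(recs, "results/recommendations.csv", row.names = FALSE)

cat("triggered technologies:\n")
for (k in which(recs$triggered)) {
  cat(sprintf("  %s\n", recs$technology[k]))
}
cat("not triggered:\n")
for (k in which(!recs$triggered)) {
  cat(sprintf("  %s (%s)\n", recs$technology[k], recs$rationale[k]))
}
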