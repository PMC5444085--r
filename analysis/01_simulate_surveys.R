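#!/usr/bin/env Rscript
# Generates the synthetic entomological data the later stages consume: one
# hourly biting survey, one blood-meal sample, one resting collection, and a
# 1000-site ensemble of behaviour profiles illustrating between-site
# heterogeneity.

suppressPackageStartupMessages(library(vectorcycle))
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(q_human = 0.5, pi_indoor = 0.8, pi_in_bed = 0.75,
                    f_livestock = 0.9, person_nights = 500,
                    blood_meals = 200, seed = 20260926L)

survey <- gen_biting_survey(cfg)
write.csv(survey, "results/biting_survey.csv", row.names = FALSE)

meals <- gen_bloodmeals(cfg)
write.csv(data.frame(host = names(meals), count = as.integer(meals)),
          "results/bloodmeals.csv", row.names = FALSE)

# resting collection drawn from the configured indoor-resting probability
set.seed(cfg$seed + 1L)
n_rest <- 300
indoor <- rbinom(1, n_rest, cfg$r_indoor_rest)
write.csv(data.frame(location = c("indoor", "outdoor"),
                     fed_count = c(indoor, n_rest - indoor)),
          "results/resting.csv", row.names = FALSE)

sites <- gen_site_ensemble(cfg, 1000)
site_df <- do.call(rbind, lapply(sites, function(s) as.data.frame(unclass(s))))
site_df$site <- seq_len(nrow(site_df))
write.csv(site_df, "results/site_ensemble.csv", row.names = FALSE)

cat(sprintf("survey: %d person-nights of effort, %.1f bites/person-night total exposure\n",
            cfg$person_nights,
            sum(survey$bite_rate_indoor * survey$frac_humans_indoor +
                survey$bite_rate_outdoor * (1 - survey$frac_humans_indoor))))
cat(sprintf("blood meals: %d (%d human, %d cattle, %d other)\n",
            sum(meals), meals[["human"]], meals[["cattle"]], meals[["other"]]))
cat(sprintf("site ensemble: human blood index spans %.3f-%.3f, indoor-resting spans %.0f-fold\n",
            min(site_df$q_human), max(site_df$q_human),
            max(site_df$r_indoor_rest) / min(site_df$r_indoor_rest)))
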