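get_triggers <- function(...) {
  recs <- recommend(indicator_profile(...))
  setNames(recs$triggered, recs$technology)
}

test_that("threshold rules reproduce the worked indicator scenarios", {
  t1 <- get_triggers(pi_indoor_exposure = 0.4, q_human = 0.5,
                     f_livestock_meals = 0, sleeps_indoors = TRUE)
  expect_true(t1[["housing_proofing_residential"]])

  t2 <- get_triggers(pi_indoor_exposure = 0.5, q_human = 0.2,
                     f_livestock_meals = 0, sleeps_indoors = TRUE)
  expect_false(t2[["house_entry_traps_screens_eave_devices"]])

  t3 <- get_triggers(pi_indoor_exposure = 0.5, q_human = 0.5,
                     f_livestock_meals = 0.4, owns_livestock = TRUE)
  expect_true(t3[["livestock_insecticide"]])
})

test_that("the full rules engine matches the oracle truth table exhaustively", {
  eps <- 1e-6
  fracs <- c(0, 1 / 3 - eps, 1 / 3, 1)
  bools <- c(FALSE, TRUE)
  n_checked <- 0
  for (pi_i in fracs) for (q in fracs) for (fl in fracs) {
    for (sleeps in bools) for (migrant in bools) {
      for (outdoor in bools) for (livestock in bools) {
        for (sugar in bools) for (swarm in bools) {
          got <- get_triggers(
            pi_indoor_exposure = pi_i, q_human = q, f_livestock_meals = fl,
            sugar_labelling_positive = sugar, swarm_labelling_positive = swarm,
            sleeps_indoors = sleeps, migrant_shelters = migrant,
            outdoor_night_activity = outdoor, owns_livestock = livestock)
          want <- oracle_triggers(pi_i, pi_i, q, fl, sugar, swarm,
                                  sleeps, migrant, outdoor, livestock)
          expect_identical(got, want)
          n_checked <- n_checked + 1
        }
      }
    }
  }
  expect_equal(n_checked, length(fracs)^3 * 2^6)
})

test_that("boundary inclusion follows 'at least one-third' exactly", {
  at <- get_triggers(pi_indoor_exposure = 1 / 3, q_human = 1 / 3,
                     f_livestock_meals = 1 / 3, sleeps_indoors = TRUE,
                     owns_livestock = TRUE)
  expect_true(at[["housing_proofing_residential"]])
  expect_true(at[["house_entry_traps_screens_eave_devices"]])
  expect_true(at[["livestock_insecticide"]])
  below <- get_triggers(pi_indoor_exposure = 1 / 3 - 1e-9, q_human = 1,
                        f_livestock_meals = 1, sleeps_indoors = TRUE)
  expect_false(below[["housing_proofing_residential"]])
})

test_that("historical indoor exposure can trigger indoor rules but not the outdoor one", {
  hist <- get_triggers(pi_indoor_exposure = 0.1, q_human = 1,
                       f_livestock_meals = 0,
                       pi_indoor_exposure_historical = 0.8,
                       sleeps_indoors = TRUE, outdoor_night_activity = TRUE)
  expect_true(hist[["housing_proofing_residential"]])
  # outdoor rule uses *current* exposure: 1 - 0.1 = 0.9 >= 1/3
  expect_true(hist[["treated_clothing_emanators"]])

  cur_high_hist_low <- get_triggers(
    pi_indoor_exposure = 0.9, q_human = 1, f_livestock_meals = 0,
    pi_indoor_exposure_historical = 0.1,
    sleeps_indoors = TRUE, outdoor_night_activity = TRUE)
  expect_false(cur_high_hist_low[["treated_clothing_emanators"]])
})

test_that("raising a fraction never untriggers a satisfied technology", {
  set.seed(77)
  for (rep in 1:30) {
    pi_i <- runif(1); q <- runif(1); fl <- runif(1)
    base <- get_triggers(pi_indoor_exposure = pi_i, q_human = q,
                         f_livestock_meals = fl, sleeps_indoors = TRUE,
                         migrant_shelters = TRUE, owns_livestock = TRUE,
                         sugar_labelling_positive = TRUE,
                         swarm_labelling_positive = TRUE)
    up_q <- get_triggers(pi_indoor_exposure = pi_i,
                         q_human = min(1, q + runif(1) * (1 - q)),
                         f_livestock_meals = fl, sleeps_indoors = TRUE,
                         migrant_shelters = TRUE, owns_livestock = TRUE,
                         sugar_labelling_positive = TRUE,
                         swarm_labelling_positive = TRUE)
    up_fl <- get_triggers(pi_indoor_exposure = pi_i, q_human = q,
                          f_livestock_meals = min(1, fl + runif(1) * (1 - fl)),
                          sleeps_indoors = TRUE, migrant_shelters = TRUE,
                          owns_livestock = TRUE,
                          sugar_labelling_positive = TRUE,
                          swarm_labelling_positive = TRUE)
    # q and f_livestock enter every rule monotonically, so anything triggered
    # at the base values must remain triggered after raising them
    was_on <- names(base)[base]
    expect_true(all(up_q[was_on]))
    expect_true(all(up_fl[was_on]))
  }
})

test_that("rationale strings name each passed and failed condition", {
  recs <- recommend(indicator_profile(
    pi_indoor_exposure = 0.5, q_human = 0.2, f_livestock_meals = 0,
    sleeps_indoors = TRUE))
  entry <- recs[recs$technology == "house_entry_traps_screens_eave_devices", ]
  expect_match(entry$rationale, "indoor exposure >= 1/3: pass")
  expect_match(entry$rationale, "human blood index >= 1/3: fail")
})
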