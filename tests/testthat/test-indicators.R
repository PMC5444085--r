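test_that("human blood index point estimates and boundaries behave", {
  est <- human_blood_index(c(human = 50, livestock = 50))
  expect_equal(est$estimate, 0.5)
  zero <- human_blood_index(c(human = 0, livestock = 20))
  expect_equal(zero$estimate, 0)
  expect_equal(zero$lower, 0)
  expect_error(human_blood_index(c(human = 0, livestock = 0)), "positive")
  expect_error(human_blood_index(c(10, 20)), "named")
})

test_that("score intervals match an independent inversion of the score test", {
  cases <- list(c(30, 40), c(12, 40), c(1, 10), c(199, 200), c(0, 40))
  for (cs in cases) {
    x <- cs[1]; n <- cs[2]
    est <- human_blood_index(c(human = x, cattle = n - x))
    oracle <- score_interval_oracle(x, n)
    expect_equal(est$lower, unname(oracle["lower"]), tolerance = 1e-9)
    expect_equal(est$upper, unname(oracle["upper"]), tolerance = 1e-9)
    expect_true(est$lower <= est$estimate && est$estimate <= est$upper)
  }
})

test_that("mixed blood meals are split fractionally between hosts", {
  est <- human_blood_index(c(human = 10, cattle = 10, `human+cattle` = 10))
  expect_equal(est$estimate, 15 / 30)
  est2 <- human_blood_index(c(human = 10, cattle = 10, `human+cattle` = 10),
                            mixed_weight = 1)
  expect_equal(est2$estimate, 20 / 30)
})

test_that("exposure distribution recovers symmetric and degenerate cases", {
  sym <- data.frame(hour = 0:23, bite_rate_indoor = 2, bite_rate_outdoor = 2,
                    frac_humans_indoor = 0.5, frac_humans_in_bed = 0.2)
  expect_equal(exposure_distribution(sym)$pi_indoor, 0.5)

  indoor_only <- data.frame(
    hour = 0:23, bite_rate_indoor = c(rep(0, 20), 3, 3, 3, 3),
    bite_rate_outdoor = c(rep(0, 20), 3, 3, 3, 3),
    frac_humans_indoor = c(rep(0, 20), 1, 1, 1, 1),
    frac_humans_in_bed = 0)
  expect_equal(exposure_distribution(indoor_only)$pi_indoor, 1)

  none <- sym
  none$bite_rate_indoor <- 0
  none$bite_rate_outdoor <- 0
  expect_error(exposure_distribution(none), "all-zero exposure")
})

test_that("exposure distribution agrees with per-hour brute force", {
  set.seed(31)
  for (rep in 1:20) {
    sv <- random_survey()
    got <- exposure_distribution(sv)
    want <- exposure_oracle(sv)
    expect_equal(got$pi_indoor, want$pi_indoor, tolerance = 1e-12)
    expect_equal(got$pi_in_bed, want$pi_in_bed, tolerance = 1e-12)
    # invariance to rescaling all biting rates
    sv2 <- sv
    sc <- runif(1, 0.1, 50)
    sv2$bite_rate_indoor <- sv2$bite_rate_indoor * sc
    sv2$bite_rate_outdoor <- sv2$bite_rate_outdoor * sc
    expect_equal(exposure_distribution(sv2)$pi_indoor, got$pi_indoor,
                 tolerance = 1e-12)
  }
})

test_that("excluding in-bed exposure models protected net users", {
  sv <- data.frame(hour = 0:23, bite_rate_indoor = 1, bite_rate_outdoor = 1,
                   frac_humans_indoor = 0.6, frac_humans_in_bed = 0.6)
  ed <- exposure_distribution(sv, net_users_protected_in_bed = TRUE)
  expect_equal(ed$pi_indoor, 0)  # all indoor time is in bed, hence protected
})

test_that("screening shifts residual exposure outdoors as its efficacy grows", {
  # nine-to-one indoor:outdoor exposure, 90% screening: 1 / (1 + 0.9)
  sv <- data.frame(hour = 0:23, bite_rate_indoor = 9, bite_rate_outdoor = 1,
                   frac_humans_indoor = 0.5, frac_humans_in_bed = 0.1)
  expect_equal(residual_outdoor_fraction(sv, 0.9), 1 / 1.9, tolerance = 1e-12)
  ed <- exposure_distribution(sv)
  expect_equal(residual_outdoor_fraction(sv, 0), 1 - ed$pi_indoor)
  expect_equal(residual_outdoor_fraction(sv, 1), 1)
  effs <- seq(0, 1, by = 0.1)
  vals <- vapply(effs, residual_outdoor_fraction, numeric(1), survey = sv)
  expect_true(all(diff(vals) > 0))
})

test_that("indoor resting fraction is a proportion with a score interval", {
  expect_equal(indoor_resting_fraction(25, 25)$estimate, 0.5)
  expect_equal(indoor_resting_fraction(0, 40)$estimate, 0)
  est <- indoor_resting_fraction(12, 28)
  oracle <- score_interval_oracle(12, 40)
  expect_equal(est$lower, unname(oracle["lower"]), tolerance = 1e-9)
  expect_equal(est$upper, unname(oracle["upper"]), tolerance = 1e-9)
  expect_match(est$note, "usage rate")
  expect_error(indoor_resting_fraction(0, 0), "positive")
})

test_that("survey validation rejects malformed tables", {
  sv <- random_survey()
  expect_error(validate_survey <- exposure_distribution(sv[-1, ]), "24 rows")
  bad <- sv
  bad$frac_humans_in_bed <- bad$frac_humans_indoor + 0.1
  expect_error(exposure_distribution(bad), "cannot exceed")
  neg <- sv
  neg$bite_rate_indoor[3] <- -1
  expect_error(exposure_distribution(neg), "non-negative")
})

test_that("CSV readers round-trip the fixed schemas", {
  sv <- random_survey()
  f <- tempfile(fileext = ".csv")
  write.csv(sv, f, row.names = FALSE)
  back <- read_biting_survey(f)
  expect_equal(back$bite_rate_indoor, sv$bite_rate_indoor)

  bm <- tempfile(fileext = ".csv")
  writeLines("host,count\nhuman,30\ncattle,10", bm)
  counts <- read_bloodmeals(bm)
  expect_equal(unname(counts["human"]), 30)
  expect_equal(human_blood_index(counts)$estimate, 0.75)

  rs <- tempfile(fileext = ".csv")
  writeLines("location,fed_count\nindoor,12\noutdoor,28", rs)
  rest <- read_resting(rs)
  expect_equal(indoor_resting_fraction(rest["indoor"], rest["outdoor"])$estimate,
               0.3)

  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_bloodmeals(bad), "host, count")
  unlink(c(f, bm, rs, bad))
})
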