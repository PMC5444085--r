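base_profile <- function() {
  behaviour_profile(q_human = 0.5, pi_indoor = 0.9, pi_in_bed = 1,
                    f_livestock = 1, r_indoor_rest = 0.3)
}

test_that("an empty stack yields a single baseline layer with T = 1", {
  tr <- apply_stack(base_profile(), list())
  expect_equal(nrow(tr$summary), 1L)
  expect_equal(tr$summary$T_rel, 1)
  expect_equal(tr$summary$intervention, "baseline")
  expect_equal(sum(tr$residual[1, ]), 1)
})

test_that("blocking nets push residual blood meals onto livestock", {
  p <- base_profile()
  tr <- apply_stack(p, list(intervention("LLIN", 0.8, block = 0.625)))
  baseline_share <- tr$residual["layer0", "livestock"]
  expect_equal(unname(baseline_share), 0.5)
  expect_gt(tr$residual["layer1", "livestock"], baseline_share)
  # direction confirmed by direct simulation of the attempt rules
  sim <- mc_cycle(p, list(intervention("LLIN", 0.8, block = 0.625)),
                  n = 4e4, seed = 11)
  sim_share <- sim$p_fed[["livestock"]] / sum(sim$p_fed)
  expect_gt(sim_share, 0.5)
  expect_lt(abs(sim_share - tr$residual["layer1", "livestock"]), 0.02)
})

test_that("each effective layer strictly reduces the transmission proxy", {
  tr <- apply_stack(base_profile(), list(
    intervention("LLIN", 0.8, block = 0.625),
    intervention("LIVESTOCK_INSECTICIDE", 0.6, post_kill = 0.8)
  ))
  T_ <- tr$summary$T_rel
  expect_equal(T_[1], 1)
  expect_lt(T_[2], T_[1])
  expect_lt(T_[3], T_[2])
})

test_that("inert layers leave every trace quantity unchanged", {
  p <- base_profile()
  base <- apply_stack(p, list())
  for (inert in list(intervention("LLIN", coverage = 0),
                     intervention("IRS", coverage = 0.8, post_kill = 0),
                     intervention("EMANATOR", coverage = 0, pre_kill = 0.5))) {
    tr <- apply_stack(p, list(inert))
    expect_equal(tr$summary$T_rel[2], 1)
    expect_equal(tr$outcomes[[2]]$p_fed, base$outcomes[[1]]$p_fed)
    expect_equal(tr$outcomes[[2]]$e_expected, 1)
    expect_equal(tr$outcomes[[2]]$p_cycle_survival, 1)
  }
})

test_that("remeasuring an untouched population returns the original profile", {
  set.seed(5)
  for (rep in 1:25) {
    p <- random_profile()
    w <- attempt_weights(p)
    # fields are only identifiable when their compartments carry weight
    out <- single_cycle(p, list())
    back <- remeasure(out)
    expect_equal(back$q_human, p$q_human, tolerance = 1e-12)
    if (p$q_human > 0) {
      expect_equal(back$pi_indoor, p$pi_indoor, tolerance = 1e-12)
      if (p$pi_indoor > 0) {
        expect_equal(back$pi_in_bed, p$pi_in_bed, tolerance = 1e-12)
      }
    }
    if (p$q_human < 1) {
      expect_equal(back$f_livestock, p$f_livestock, tolerance = 1e-12)
    }
    expect_equal(back$r_indoor_rest, p$r_indoor_rest)
  }
})

test_that("remeasurement reflects intervention-driven behaviour shifts", {
  p <- base_profile()
  out <- single_cycle(p, list(intervention("LLIN", 0.8, block = 0.625)))
  post <- remeasure(out)
  expect_lt(post$q_human, p$q_human)

  screened <- single_cycle(
    behaviour_profile(0.8, 0.6, 0.5, f_livestock = 0.5),
    list(intervention("SCREENING", coverage = 1, block = 1))
  )
  expect_equal(remeasure(screened)$pi_indoor, 0)
})

test_that("remeasure refuses an outcome with no residual feeding", {
  p <- behaviour_profile(q_human = 1, pi_indoor = 1, pi_in_bed = 1)
  out <- single_cycle(p, list(intervention("SCREENING", 1, pre_kill = 1)))
  expect_equal(sum(out$p_fed), 0)
  expect_error(remeasure(out), "no residual feeding")
})

test_that("pure blocking shrinks the targeted share and grows every other", {
  set.seed(12)
  for (rep in 1:25) {
    p <- behaviour_profile(q_human = runif(1, 0.2, 0.8),
                           pi_indoor = runif(1, 0.2, 0.8),
                           pi_in_bed = runif(1, 0.2, 0.8),
                           f_livestock = runif(1, 0.2, 0.8))
    blocker <- intervention("LLIN", coverage = runif(1, 0.3, 0.95),
                            block = runif(1, 0.3, 0.95))
    m0 <- residual_meals(single_cycle(p, list()))
    m1 <- residual_meals(single_cycle(p, list(blocker)))
    expect_lt(m1[["human_indoor_in_bed"]], m0[["human_indoor_in_bed"]])
    for (j in setdiff(COMPARTMENTS, "human_indoor_in_bed")) {
      expect_gt(m1[[j]], m0[[j]])
    }
  }
})

test_that("layer errors are annotated with the offending layer", {
  p <- behaviour_profile(q_human = 1, pi_indoor = 1, pi_in_bed = 1)
  expect_error(
    apply_stack(p, list(intervention("IRS", 0.5, post_kill = 0.5),
                        intervention("LLIN", 1, block = 1))),
    "layer 2 \\(LLIN\\)")
})

test_that("the tidy trace export has one row per layer and compartment", {
  tr <- apply_stack(base_profile(), list(intervention("LLIN", 0.8, block = 0.625)))
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 2 * length(COMPARTMENTS))
  shares <- tapply(df$residual_share, df$layer, sum)
  expect_equal(as.vector(shares), c(1, 1))
})
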