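# Independent oracles used to validate the closed-form implementations.
# These deliberately re-derive everything by brute force / direct simulation
# of the stated rules and share no code with the package internals.

# Stochastic simulation of the feeding-cycle attempt process: each replicate
# mosquito repeatedly picks a compartment, meets the attack-phase
# interventions protecting it in order (kill / block / pass per encounter),
# feeds if it passes everything, and then runs the post-feed hazard gauntlet.
mc_cycle <- function(profile, interventions = list(), n = 1e5, seed = 1) {
  set.seed(seed)
  w <- attempt_weights(profile)
  comps <- names(w)
  ni <- length(interventions)
  pre_dead <- rep(FALSE, n)
  fed_comp <- rep(NA_character_, n)
  enc <- matrix(FALSE, n, max(1L, ni))
  fed_at_cov <- matrix(FALSE, n, max(1L, ni))
  attempts <- integer(n)
  active <- rep(TRUE, n)
  rounds <- 0L
  while (any(active)) {
    rounds <- rounds + 1L
    if (rounds > 10000L) stop("simulation failed to absorb (total blockade?)")
    ia <- which(active)
    m <- length(ia)
    attempts[ia] <- attempts[ia] + 1L
    comp <- sample(comps, m, replace = TRUE, prob = w)
    alive <- rep(TRUE, m)
    killed <- rep(FALSE, m)
    passed_cov <- matrix(FALSE, m, max(1L, ni))
    for (i in seq_len(ni)) {
      iv <- interventions[[i]]
      if (iv$phase != "attack") next
      mask <- alive & (comp %in% iv$targets)
      if (!any(mask)) next
      met <- mask & (runif(m) < iv$coverage)
      enc[ia[met], i] <- TRUE
      u <- runif(m)
      k <- met & (u < iv$pre_kill)
      b <- met & !k & (u < iv$pre_kill + iv$block)
      passed_cov[met & !k & !b, i] <- TRUE
      killed <- killed | k
      alive <- alive & !(k | b)
    }
    fed <- alive
    fed_comp[ia[fed]] <- comp[fed]
    if (ni) fed_at_cov[ia[fed], ] <- passed_cov[fed, , drop = FALSE]
    pre_dead[ia[killed]] <- TRUE
    active[ia[fed | killed]] <- FALSE
  }
  is_fed <- !is.na(fed_comp)
  post_dead <- rep(FALSE, n)
  indoor <- c("human_indoor_in_bed", "human_indoor_out_of_bed")
  for (i in seq_len(ni)) {
    iv <- interventions[[i]]
    if (iv$phase == "attack") {
      if (iv$post_kill > 0) {
        die <- fed_at_cov[, i] & is_fed & (runif(n) < iv$post_kill)
        post_dead <- post_dead | die
      }
      next
    }
    exposed <- switch(iv$kind,
      IRS = is_fed & (fed_comp %in% indoor) &
        (runif(n) < profile$r_indoor_rest) & (runif(n) < iv$coverage),
      LIVESTOCK_INSECTICIDE = is_fed & !is.na(fed_comp) &
        fed_comp == "livestock" & (runif(n) < iv$coverage),
      SUGAR_BAIT = is_fed & (runif(n) < profile$sugar_rate) &
        (runif(n) < iv$coverage),
      SWARM_SPRAY = is_fed & (runif(n) < iv$coverage))
    enc[exposed, i] <- TRUE
    post_dead <- post_dead | (exposed & (runif(n) < iv$post_kill))
  }
  list(
    n = n,
    p_pre_death = mean(pre_dead),
    p_fed = vapply(comps, function(j) mean(!is.na(fed_comp) & fed_comp == j),
                   numeric(1)),
    p_post_death = if (any(is_fed)) mean(post_dead[is_fed]) else 0,
    e_expected = mean(attempts),
    c_m = colMeans(enc)[seq_len(ni)]
  )
}

# binomial standard error under the closed-form null, floored at 1/n so
# that zero observed counts of a rare fate are handled sensibly
mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1 / n) / n)

# expects every fate probability of the closed form to sit within k Monte
# Carlo standard errors (computed at the closed-form value) of the
# simulated one
expect_matches_mc <- function(outcome, sim, k = 3) {
  expect_lt(abs(outcome$p_pre_death - sim$p_pre_death),
            k * mc_se(outcome$p_pre_death, sim$n))
  for (j in names(outcome$p_fed)) {
    expect_lt(abs(outcome$p_fed[[j]] - sim$p_fed[[j]]),
              k * mc_se(outcome$p_fed[[j]], sim$n))
  }
  expect_lt(abs(outcome$p_post_death - sim$p_post_death),
            k * mc_se(outcome$p_post_death, sim$n))
  for (i in seq_along(outcome$c_m)) {
    expect_lt(abs(outcome$c_m[[i]] - sim$c_m[[i]]),
              k * mc_se(outcome$c_m[[i]], sim$n))
  }
}

# Wilson score interval by direct numerical inversion of the score test:
# the endpoints are the roots of (phat - p)^2 = z^2 p (1 - p) / n
score_interval_oracle <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  lower <- if (phat <= 0) 0 else
    uniroot(f, c(0, phat * (1 - 1e-12)), tol = 1e-13)$root
  upper <- if (phat >= 1) 1 else
    uniroot(f, c(max(phat, 1e-9), 1), tol = 1e-13)$root
  c(lower = lower, upper = upper)
}

# plain per-hour summation of exposure weights, written independently of
# exposure_distribution
exposure_oracle <- function(survey) {
  win <- 0; wout <- 0; wbed <- 0
  for (r in seq_len(nrow(survey))) {
    row <- survey[survey$hour == r - 1, ]
    win <- win + row$bite_rate_indoor * row$frac_humans_indoor
    wout <- wout + row$bite_rate_outdoor * (1 - row$frac_humans_indoor)
    wbed <- wbed + row$bite_rate_indoor * row$frac_humans_in_bed
  }
  list(pi_indoor = win / (win + wout),
       pi_in_bed = if (win > 0) wbed / win else 0)
}

# independent restatement of the opportunity-threshold rules, written as a
# literal condition table against which the engine is checked exhaustively
oracle_triggers <- function(pi_ind, pi_cur, q, fl, sugar, swarm,
                            sleeps, migrant, outdoor, livestock) {
  third <- function(x) 3 * x >= 1
  c(
    housing_proofing_residential = sleeps && third(pi_ind),
    housing_proofing_shelters = migrant && third(pi_ind),
    house_entry_traps_screens_eave_devices =
      (sleeps || migrant) && third(pi_ind) && third(q),
    treated_clothing_emanators = outdoor && third(1 - pi_cur),
    livestock_insecticide = livestock && third(fl),
    sugar_baits = sugar,
    swarm_sprays = swarm
  )
}

random_profile <- function() {
  behaviour_profile(
    q_human = runif(1), pi_indoor = runif(1), pi_in_bed = runif(1),
    f_livestock = runif(1), r_indoor_rest = runif(1), sugar_rate = runif(1)
  )
}

random_survey <- function() {
  h_in <- pmin(1, pmax(0, runif(24)))
  data.frame(
    hour = 0:23,
    bite_rate_indoor = rgamma(24, 2, 1),
    bite_rate_outdoor = rgamma(24, 2, 1),
    frac_humans_indoor = h_in,
    frac_humans_in_bed = h_in * runif(24)
  )
}

random_stack <- function(max_layers = 3) {
  kinds <- sample(INTERVENTION_KINDS, sample.int(max_layers, 1))
  lapply(kinds, function(k) {
    pk <- runif(1, 0, 0.5)
    intervention(k, coverage = runif(1), pre_kill = pk,
                 block = runif(1, 0, 1 - pk), post_kill = runif(1))
  })
}
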