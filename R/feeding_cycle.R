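#' Default per-encounter non-lethal block probability for bed nets
#'
#' Per-encounter probability that an attack on a protected, net-using host is
#' blocked without killing the mosquito. The default 0.625 is calibrated so
#' that 80% net usage doubles the number of host encounters (equivalently,
#' houses entered) a mosquito needs per blood meal, matching field
#' observations of repeated house entry under high net coverage. Equivalent
#' to a per-protected-host feeding success of 0.375. Overridable everywhere
#' it is used.
#'
#' @export
LLIN_BLOCK_DEFAULT <- 0.625

#' Expected host encounters per blood meal under partial protection
#'
#' When a fraction `u` of a host class is protected and each attack on a
#' protected host is blocked non-lethally with probability `b`, the relative
#' availability of that host's blood is `z = 1 - u*b` and a mosquito needs on
#' average `1/z` encounters (geometric waiting time) to obtain one blood
#' meal. With 80% net usage and the calibrated block probability
#' [LLIN_BLOCK_DEFAULT], encounters double relative to the no-net baseline.
#'
#' @param u Usage/coverage of protection among the host class, in `[0, 1]`.
#' @param b Per-encounter probability that an attack on a protected host is
#'   blocked non-lethally. Defaults to [LLIN_BLOCK_DEFAULT].
#' @return An object of class `encounter_model` with fields `u`, `b`,
#'   `z_relative` (`1 - u*b`) and `e_expected` (`1 / z_relative`).
#' @examples
#' expected_encounters(0.8)$e_expected   # 2: encounter doubling at 80% usage
#' expected_encounters(0)$e_expected     # 1: no protection
#' @export
expected_encounters <- function(u, b = LLIN_BLOCK_DEFAULT) {
  u <- check_prob(u, "u")
  b <- check_prob(b, "b")
  z <- 1 - u * b
  if (z <= PROB_TOL) {
    stop("total blockade: u * b >= 1 leaves no feeding possible", call. = FALSE)
  }
  structure(list(u = u, b = b, z_relative = z, e_expected = 1 / z),
            class = "encounter_model")
}

#' @export
print.encounter_model <- function(x, ...) {
  cat(sprintf("<encounter_model> u=%.3f b=%.3f  z=%.4f  E[encounters]=%.4f\n",
              x$u, x$b, x$z_relative, x$e_expected))
  invisible(x)
}

#' Mosquito population coverage of a house-delivered insecticide
#'
#' Probability that a mosquito is exposed to a house-delivered insecticide
#' (such as a residual wall spray) at least once per feeding cycle, when a
#' fraction `c_h` of houses is covered and the mosquito makes `e` independent
#' house entries per blood meal: `C_M = q * (1 - (1 - pi_indoor * c_h)^e)`,
#' where `q` is the human blood index and `pi_indoor` the proportion of
#' human attacks that would occur indoors absent protection. At `e = 1` this
#' reduces to the simple product `q * pi_indoor * c_h`; larger `e` (e.g.
#' driven by high bed-net usage, see [expected_encounters()]) amplifies
#' coverage at any intermediate `c_h`.
#'
#' @param c_h House coverage in `[0, 1]`.
#' @param profile A [behaviour_profile()]; only `q_human` and `pi_indoor`
#'   are used.
#' @param e Expected house entries per blood meal, `>= 1`.
#' @return Population coverage `C_M` in `[0, 1]`.
#' @examples
#' p <- behaviour_profile(1, 0.9, 1)
#' population_coverage(1, p, e = 1)    # 0.9 = pi_indoor at full coverage
#' population_coverage(0.5, p, e = 2)  # net-amplified coverage
#' @export
population_coverage <- function(c_h, profile, e = 1) {
  c_h <- check_prob(c_h, "c_h")
  stopifnot(inherits(profile, "behaviour_profile"))
  if (!is.numeric(e) || length(e) != 1 || is.na(e) || e < 1) {
    stop("'e' must be a single number >= 1", call. = FALSE)
  }
  profile$q_human * (1 - (1 - profile$pi_indoor * c_h)^e)
}

# per-attempt hazard decomposition for one compartment: walks the ordered
# attack-phase interventions protecting j and returns the per-attempt kill,
# block and feed-through probabilities (conditional on attempting j), the
# pass-through probability in front of each intervention, and the
# conditional probability that a mosquito which fed on j had encountered
# each intervention's coverage
attack_ladder <- function(j, interventions) {
  idx <- which(vapply(interventions, function(iv) {
    iv$phase == "attack" && j %in% iv$targets
  }, logical(1)))
  pass <- 1
  kill <- 0
  block <- 0
  reach <- setNames(numeric(length(idx)), idx)
  for (k in seq_along(idx)) {
    iv <- interventions[[idx[k]]]
    reach[k] <- pass
    kill  <- kill + pass * iv$coverage * iv$pre_kill
    block <- block + pass * iv$coverage * iv$block
    pass  <- pass * (1 - iv$coverage * (iv$pre_kill + iv$block))
  }
  enc_given_fed <- vapply(idx, function(i) {
    iv <- interventions[[i]]
    denom <- 1 - iv$coverage * (iv$pre_kill + iv$block)
    if (denom <= 0) 0 else iv$coverage * (1 - iv$pre_kill - iv$block) / denom
  }, numeric(1))
  list(idx = idx, kill = kill, block = block, feed = pass,
       reach = reach, enc_given_fed = setNames(enc_given_fed, idx))
}

#' Closed-form fate probabilities for one feeding cycle
#'
#' Solves a single gonotrophic cycle as an absorbing process over repeated
#' attack attempts. Each attempt is directed at compartment `j` with the
#' baseline weight from [attempt_weights()]; attack-phase interventions
#' protecting `j` are met in their listed order, each killing the mosquito
#' before it feeds, blocking it non-lethally (a fresh attempt follows) or
#' letting it through; uncovered attacks always feed. Blocking inflates the
#' expected number of attempts geometrically. Post-phase mortality (wall
#' sprays met while resting indoors after an indoor feed, insecticide-treated
#' livestock, toxic sugar baits, swarm sprays) then compounds as independent
#' hazards on the fed mosquitoes.
#'
#' @param profile A [behaviour_profile()].
#' @param interventions Ordered list of [intervention()] objects (possibly
#'   empty).
#' @return An object of class `cycle_outcome` with fields
#'   \describe{
#'     \item{p_pre_death}{probability of death before feeding in the cycle}
#'     \item{p_fed}{named vector: probability of successfully feeding in each
#'       compartment (`p_pre_death + sum(p_fed) == 1`)}
#'     \item{p_post_death}{probability of death between feeding and the next
#'       cycle, conditional on having fed}
#'     \item{p_cycle_survival}{`(1 - p_pre_death) * (1 - p_post_death)`}
#'     \item{e_expected}{expected attack attempts per blood meal}
#'     \item{c_m}{per-intervention population coverage: probability of
#'       encountering that intervention at least once during the cycle}
#'   }
#' @examples
#' p <- behaviour_profile(0.5, 0.9, 1, f_livestock = 1)
#' single_cycle(p, list(intervention("LLIN", 0.8, block = 0.625)))
#' @export
single_cycle <- function(profile, interventions = list()) {
  stopifnot(inherits(profile, "behaviour_profile"))
  interventions <- as_intervention_list(interventions)
  w <- attempt_weights(profile)

  ladders <- lapply(COMPARTMENTS, attack_ladder, interventions = interventions)
  names(ladders) <- COMPARTMENTS

  kill_j  <- vapply(ladders, `[[`, numeric(1), "kill")
  block_j <- vapply(ladders, `[[`, numeric(1), "block")
  feed_j  <- vapply(ladders, `[[`, numeric(1), "feed")

  K <- sum(w * kill_j)
  B <- sum(w * block_j)
  F_j <- w * feed_j
  if (B >= 1 - PROB_TOL) {
    stop("total blockade: every attempt is blocked, no feeding or death possible",
         call. = FALSE)
  }
  p_pre_death <- K / (1 - B)
  p_fed <- F_j / (1 - B)
  e_expected <- 1 / (1 - B)

  # post-feed survival per compartment: independent hazards
  surv_j <- setNames(rep(1, length(COMPARTMENTS)), COMPARTMENTS)
  for (i in seq_along(interventions)) {
    iv <- interventions[[i]]
    for (j in COMPARTMENTS) {
      hazard <- 0
      if (iv$phase == "attack") {
        if (j %in% iv$targets && iv$post_kill > 0) {
          hazard <- ladders[[j]]$enc_given_fed[[as.character(i)]] * iv$post_kill
        }
      } else {
        hazard <- switch(iv$kind,
          IRS = if (j %in% INDOOR_COMPARTMENTS)
            profile$r_indoor_rest * iv$coverage * iv$post_kill else 0,
          LIVESTOCK_INSECTICIDE = if (j == "livestock")
            iv$coverage * iv$post_kill else 0,
          SUGAR_BAIT = profile$sugar_rate * iv$coverage * iv$post_kill,
          SWARM_SPRAY = iv$coverage * iv$post_kill,
          0)
      }
      surv_j[j] <- surv_j[j] * (1 - hazard)
    }
  }
  fed_total <- sum(p_fed)
  p_post_death <- if (fed_total > 0) {
    sum((p_fed / fed_total) * (1 - surv_j))
  } else 0

  c_m <- cycle_cm(w, ladders, p_fed, profile, interventions)

  structure(
    list(p_pre_death = p_pre_death, p_fed = p_fed,
         p_post_death = p_post_death,
         p_cycle_survival = (1 - p_pre_death) * (1 - p_post_death),
         e_expected = e_expected, c_m = c_m,
         profile = profile, interventions = interventions),
    class = "cycle_outcome"
  )
}

# probability of >= 1 encounter with each intervention over the whole cycle:
# attack kinds via the absorbing chain (an attempt either encounters i, is
# blocked without encountering i, or absorbs without encountering i, so
# C_M = m / (1 - nb)); post kinds as the exposure probability of the hazard
cycle_cm <- function(w, ladders, p_fed, profile, interventions) {
  if (!length(interventions)) return(numeric(0))
  c_m <- numeric(length(interventions))
  fed_indoor <- sum(p_fed[INDOOR_COMPARTMENTS])
  fed_total <- sum(p_fed)
  for (i in seq_along(interventions)) {
    iv <- interventions[[i]]
    if (iv$phase == "post") {
      c_m[i] <- switch(iv$kind,
        IRS = fed_indoor * profile$r_indoor_rest * iv$coverage,
        LIVESTOCK_INSECTICIDE = p_fed[["livestock"]] * iv$coverage,
        SUGAR_BAIT = fed_total * profile$sugar_rate * iv$coverage,
        SWARM_SPRAY = fed_total * iv$coverage)
      next
    }
    m_i <- 0   # per-attempt P(encounter i)
    nb_i <- 0  # per-attempt P(blocked, i not encountered)
    for (j in COMPARTMENTS) {
      lad <- ladders[[j]]
      if (i %in% lad$idx) {
        m_i <- m_i + w[[j]] * lad$reach[[as.character(i)]] * iv$coverage
        # walk the ladder tracking the "i not yet encountered" branch
        pass_noenc <- 1
        for (k in lad$idx) {
          ivk <- interventions[[k]]
          if (k == i) {
            pass_noenc <- pass_noenc * (1 - ivk$coverage)
          } else {
            nb_i <- nb_i + w[[j]] * pass_noenc * ivk$coverage * ivk$block
            pass_noenc <- pass_noenc *
              (1 - ivk$coverage * (ivk$pre_kill + ivk$block))
          }
        }
      } else {
        nb_i <- nb_i + w[[j]] * lad$block
      }
    }
    c_m[i] <- if (nb_i >= 1) 1 else m_i / (1 - nb_i)
  }
  names(c_m) <- vapply(interventions, `[[`, character(1), "kind")
  c_m
}

#' Residual blood-meal distribution of a cycle outcome
#'
#' Renormalises the per-compartment feeding probabilities of a
#' [single_cycle()] outcome to the distribution of successful blood meals —
#' what a blood-meal survey of fed mosquitoes would observe.
#'
#' @param outcome A `cycle_outcome`.
#' @return Named numeric vector over [COMPARTMENTS] summing to 1.
#' @export
residual_meals <- function(outcome) {
  stopifnot(inherits(outcome, "cycle_outcome"))
  tot <- sum(outcome$p_fed)
  if (tot <= 0) {
    stop("no residual feeding: all mosquitoes die before feeding", call. = FALSE)
  }
  outcome$p_fed / tot
}

#' @export
print.cycle_outcome <- function(x, ...) {
  cat("<cycle_outcome>\n")
  cat(sprintf("  p_pre_death      %.4f\n", x$p_pre_death))
  for (j in names(x$p_fed)) cat(sprintf("  p_fed[%-23s] %.4f\n", j, x$p_fed[[j]]))
  cat(sprintf("  p_post_death     %.4f (given fed)\n", x$p_post_death))
  cat(sprintf("  p_cycle_survival %.4f\n", x$p_cycle_survival))
  cat(sprintf("  e_expected       %.4f attempts per meal\n", x$e_expected))
  if (length(x$c_m)) {
    cat("  per-intervention coverage (C_M):\n")
    for (i in seq_along(x$c_m)) {
      cat(sprintf("    %-22s %.4f\n", names(x$c_m)[i], x$c_m[[i]]))
    }
  }
  invisible(x)
}
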