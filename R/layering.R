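#' Sequential layering of interventions with behavioural redistribution
#'
#' Applies an ordered stack of interventions one layer at a time, computing
#' the feeding-cycle outcome of each cumulative prefix with [single_cycle()].
#' The trace records, per layer, the fate probabilities, the residual
#' blood-meal distribution (showing how surviving meals concentrate on
#' untargeted compartments — the plastic "push" of push-pull layering) and a
#' relative transmission proxy
#' `T_k = (h_k / (1 - S_k)) / (h_0 / (1 - S_0))`, where `h_k` is the
#' probability of feeding on a human in the cycle and
#' `S_k = baseline_survival * (1 - p_pre_death) * (1 - p_post_death)` the
#' per-cycle survival; `h / (1 - S)` is the expected number of lifetime human
#' feeds under geometric survival. `T_0 = 1` by construction.
#'
#' @param profile A [behaviour_profile()].
#' @param stack Ordered list of [intervention()] objects.
#' @param baseline_survival Background probability of surviving one feeding
#'   cycle absent any intervention (flight, predation, gonotrophic losses).
#'   Default 0.7, a field-plausible value for African vectors (daily survival
#'   around 0.89 over a three-day cycle).
#' @return An object of class `layer_trace`: a list with `outcomes` (one
#'   `cycle_outcome` per layer, layer 0 = baseline), `summary` (data frame,
#'   one row per layer: fate probabilities, human-feed probability `h`,
#'   per-cycle survival `S`, transmission proxy `T_rel`) and `residual`
#'   (matrix of residual meal shares, layers x compartments).
#' @examples
#' p <- behaviour_profile(0.5, 0.9, 1, f_livestock = 1, r_indoor_rest = 0.3)
#' tr <- apply_stack(p, list(
#'   intervention("LLIN", 0.8, block = 0.625),
#'   intervention("LIVESTOCK_INSECTICIDE", 0.6, post_kill = 0.8)
#' ))
#' tr$summary
#' @export
apply_stack <- function(profile, stack = list(), baseline_survival = 0.7) {
  stopifnot(inherits(profile, "behaviour_profile"))
  stack <- as_intervention_list(stack)
  baseline_survival <- check_prob(baseline_survival, "baseline_survival")
  n <- length(stack)
  outcomes <- vector("list", n + 1L)
  for (k in 0:n) {
    outcomes[[k + 1L]] <- tryCatch(
      single_cycle(profile, stack[seq_len(k)]),
      error = function(e) {
        stop(sprintf("layer %d (%s): %s", k,
                     if (k > 0) stack[[k]]$kind else "baseline",
                     conditionMessage(e)), call. = FALSE)
      })
  }
  h <- vapply(outcomes, function(o) sum(o$p_fed[HUMAN_COMPARTMENTS]), numeric(1))
  S <- vapply(outcomes, function(o) {
    baseline_survival * (1 - o$p_pre_death) * (1 - o$p_post_death)
  }, numeric(1))
  lifetime_feeds <- h / (1 - S)
  T_rel <- lifetime_feeds / lifetime_feeds[1]

  residual <- t(vapply(outcomes, function(o) {
    tot <- sum(o$p_fed)
    if (tot > 0) o$p_fed / tot else rep(NA_real_, length(COMPARTMENTS))
  }, numeric(length(COMPARTMENTS))))
  rownames(residual) <- paste0("layer", 0:n)

  summary <- data.frame(
    layer = 0:n,
    intervention = c("baseline", vapply(stack, `[[`, character(1), "kind")),
    p_pre_death = vapply(outcomes, `[[`, numeric(1), "p_pre_death"),
    p_post_death = vapply(outcomes, `[[`, numeric(1), "p_post_death"),
    e_expected = vapply(outcomes, `[[`, numeric(1), "e_expected"),
    h_human_feed = h,
    S_cycle = S,
    T_rel = T_rel,
    stringsAsFactors = FALSE
  )
  structure(list(outcomes = outcomes, summary = summary, residual = residual,
                 baseline_survival = baseline_survival),
            class = "layer_trace")
}

#' @export
print.layer_trace <- function(x, ...) {
  cat("<layer_trace> ", nrow(x$summary), "layers\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Post-intervention behaviour profile implied by residual meals
#'
#' Inverts the residual blood-meal distribution of a cycle outcome back into
#' the behaviour profile a field survey would now observe: the
#' post-intervention human blood index, indoor and in-bed exposure fractions
#' and livestock share of animal meals. Fractions whose denominator vanishes
#' (e.g. the in-bed split after a complete indoor blockade) and the
#' non-meal-identifiable fields (`r_indoor_rest`, `sugar_rate`) are carried
#' over from the baseline profile.
#'
#' @param outcome A `cycle_outcome` from [single_cycle()].
#' @param profile The baseline [behaviour_profile()] the outcome was computed
#'   from; defaults to the one stored in the outcome.
#' @return A [behaviour_profile()].
#' @examples
#' p <- behaviour_profile(0.5, 0.9, 1, f_livestock = 1)
#' out <- single_cycle(p, list(intervention("LLIN", 0.8, block = 0.625)))
#' remeasure(out)$q_human  # below 0.5: meals pushed onto cattle
#' @export
remeasure <- function(outcome, profile = outcome$profile) {
  m <- residual_meals(outcome)
  q <- sum(m[HUMAN_COMPARTMENTS])
  indoor <- sum(m[INDOOR_COMPARTMENTS])
  animal <- m[["livestock"]] + m[["other_animal"]]
  behaviour_profile(
    q_human     = q,
    pi_indoor   = if (q > 0) indoor / q else profile$pi_indoor,
    pi_in_bed   = if (indoor > 0) m[["human_indoor_in_bed"]] / indoor
                  else profile$pi_in_bed,
    f_livestock = if (animal > 0) m[["livestock"]] / animal
                  else profile$f_livestock,
    r_indoor_rest = profile$r_indoor_rest,
    sugar_rate    = profile$sugar_rate
  )
}

#' Tidy export of a layer trace
#'
#' @param trace A `layer_trace` from [apply_stack()].
#' @return Data frame with one row per layer x compartment: layer index,
#'   intervention added, compartment, feeding probability and residual meal
#'   share.
#' @export
trace_to_df <- function(trace) {
  stopifnot(inherits(trace, "layer_trace"))
  n <- length(trace$outcomes)
  do.call(rbind, lapply(seq_len(n), function(k) {
    o <- trace$outcomes[[k]]
    data.frame(
      layer = k - 1L,
      intervention = trace$summary$intervention[k],
      compartment = COMPARTMENTS,
      p_fed = unname(o$p_fed),
      residual_share = unname(trace$residual[k, ]),
      stringsAsFactors = FALSE
    )
  }))
}
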