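#' Indicator profile for intervention selection
#'
#' Bundles the entomological indicators and human-context flags that the
#' opportunity-threshold rules act on.
#'
#' @param pi_indoor_exposure Current fraction of human exposure to vector
#'   bites occurring indoors, `[0, 1]`.
#' @param q_human Human blood index, `[0, 1]`.
#' @param f_livestock_meals Fraction of vector blood meals obtained from
#'   identified livestock species, `[0, 1]`.
#' @param pi_indoor_exposure_historical Optional historical value of the
#'   indoor exposure fraction; indoor-threshold rules accept the maximum of
#'   historical and current ("historical or current" exposure), while the
#'   outdoor rule uses current exposure only.
#' @param sugar_labelling_positive Were most vectors labelled by dyed
#'   (insecticide-free) sugar baits?
#' @param swarm_labelling_positive Were most vectors labelled by dyed swarm
#'   spray formulations?
#' @param sleeps_indoors,migrant_shelters,outdoor_night_activity,owns_livestock
#'   Human-context flags: at least partially sedentary and sleeping indoors;
#'   at least partially migrant and sleeping in shelters; outdoor activity
#'   common during hours of darkness; livestock ownership.
#' @return An object of class `indicator_profile`.
#' @export
indicator_profile <- function(pi_indoor_exposure, q_human, f_livestock_meals,
                              pi_indoor_exposure_historical = NULL,
                              sugar_labelling_positive = FALSE,
                              swarm_labelling_positive = FALSE,
                              sleeps_indoors = FALSE,
                              migrant_shelters = FALSE,
                              outdoor_night_activity = FALSE,
                              owns_livestock = FALSE) {
  pi_indoor_exposure <- check_prob(pi_indoor_exposure, "pi_indoor_exposure")
  q_human <- check_prob(q_human, "q_human")
  f_livestock_meals <- check_prob(f_livestock_meals, "f_livestock_meals")
  if (!is.null(pi_indoor_exposure_historical)) {
    pi_indoor_exposure_historical <-
      check_prob(pi_indoor_exposure_historical, "pi_indoor_exposure_historical")
  }
  flags <- list(sugar_labelling_positive, swarm_labelling_positive,
                sleeps_indoors, migrant_shelters, outdoor_night_activity,
                owns_livestock)
  if (!all(vapply(flags, function(f) is.logical(f) && length(f) == 1 && !is.na(f),
                  logical(1)))) {
    stop("context flags must be single TRUE/FALSE values", call. = FALSE)
  }
  structure(list(
    pi_indoor_exposure = pi_indoor_exposure,
    pi_indoor_exposure_historical = pi_indoor_exposure_historical,
    q_human = q_human,
    f_livestock_meals = f_livestock_meals,
    sugar_labelling_positive = sugar_labelling_positive,
    swarm_labelling_positive = swarm_labelling_positive,
    sleeps_indoors = sleeps_indoors,
    migrant_shelters = migrant_shelters,
    outdoor_night_activity = outdoor_night_activity,
    owns_livestock = owns_livestock
  ), class = "indicator_profile")
}

# "at least one-third" compared exactly as 3*x >= 1; boundary inclusion
# follows "at least", no floating tolerance applied
at_least_third <- function(x) 3 * x >= 1

#' Technology recommendations from an indicator profile
#'
#' Applies the opportunity-indicator thresholds to an [indicator_profile()]
#' and returns, for each adult-vector control technology, whether its
#' deployment conditions hold and why. Threshold rules ("at least one-third"
#' of exposure or blood meals) use the historical-or-current maximum for
#' indoor exposure and the current value for outdoor exposure; sugar baits
#' and swarm sprays are triggered by positive bait/spray labelling surveys,
#' for which no numeric threshold is established.
#'
#' @param profile An [indicator_profile()].
#' @return Data frame with one row per technology: `technology`, `triggered`
#'   and a `rationale` string listing which conditions passed or failed.
#' @examples
#' ip <- indicator_profile(pi_indoor_exposure = 0.4, q_human = 0.6,
#'                         f_livestock_meals = 0.2, sleeps_indoors = TRUE)
#' recommend(ip)
#' @export
recommend <- function(profile) {
  stopifnot(inherits(profile, "indicator_profile"))
  pi_cur <- profile$pi_indoor_exposure
  pi_ind <- max(pi_cur, profile$pi_indoor_exposure_historical %||% 0)

  cond <- function(ok, label) {
    list(ok = ok, label = sprintf("%s: %s", label, if (ok) "pass" else "fail"))
  }
  row <- function(tech, ...) {
    cs <- list(...)
    data.frame(
      technology = tech,
      triggered = all(vapply(cs, `[[`, logical(1), "ok")),
      rationale = paste(vapply(cs, `[[`, character(1), "label"),
                        collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  indoor_third <- cond(at_least_third(pi_ind),
                       "historical-or-current indoor exposure >= 1/3")
  rbind(
    row("housing_proofing_residential",
        cond(profile$sleeps_indoors, "sleeps indoors"), indoor_third),
    row("housing_proofing_shelters",
        cond(profile$migrant_shelters, "sleeps in migrant shelters"),
        indoor_third),
    row("house_entry_traps_screens_eave_devices",
        cond(profile$sleeps_indoors || profile$migrant_shelters,
             "sleeps indoors or in shelters"),
        indoor_third,
        cond(at_least_third(profile$q_human), "human blood index >= 1/3")),
    row("treated_clothing_emanators",
        cond(profile$outdoor_night_activity, "outdoor night activity"),
        cond(at_least_third(1 - pi_cur), "current outdoor exposure >= 1/3")),
    row("livestock_insecticide",
        cond(profile$owns_livestock, "owns livestock"),
        cond(at_least_third(profile$f_livestock_meals),
             "livestock blood meals >= 1/3")),
    row("sugar_baits",
        cond(profile$sugar_labelling_positive, "sugar bait labelling positive")),
    row("swarm_sprays",
        cond(profile$swarm_labelling_positive, "swarm labelling positive"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
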