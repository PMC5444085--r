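#' Behavioural blood-feeding compartments
#'
#' The five mutually exclusive compartments an attacking mosquito can direct a
#' blood-feeding attempt at: humans indoors while in bed, humans indoors but
#' out of bed, humans outdoors, treatable livestock, and other (wild or
#' untreatable) animals.
#'
#' @format Character vector of length 5.
#' @export
COMPARTMENTS <- c(
  "human_indoor_in_bed",
  "human_indoor_out_of_bed",
  "human_outdoor",
  "livestock",
  "other_animal"
)

HUMAN_COMPARTMENTS  <- COMPARTMENTS[1:3]
INDOOR_COMPARTMENTS <- COMPARTMENTS[1:2]

# tolerance for probability domain checks at API boundaries; values outside
# [0, 1] by more than this are rejected, never clamped
PROB_TOL <- 1e-9

check_prob <- function(x, name, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop(sprintf("'%s' must be a numeric value of length %d with no NAs", name, len),
         call. = FALSE)
  }
  if (any(x < -PROB_TOL) || any(x > 1 + PROB_TOL)) {
    stop(sprintf("'%s' must lie in [0, 1] (got %s)", name,
                 paste(signif(x, 6), collapse = ", ")), call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

#' Baseline behaviour profile of a vector population
#'
#' Describes where a vector population obtains its blood meals and what it
#' does around them, in the absence of any intervention. The six fractions
#' jointly determine the baseline attempt weights over the five blood-feeding
#' compartments (see [attempt_weights()]).
#'
#' @param q_human Human blood index: fraction of blood meals taken on humans.
#' @param pi_indoor Proportion of human exposure occurring indoors in the
#'   absence of any protection (the quantity usually written pi_h,i,0).
#' @param pi_in_bed Proportion of *indoor* human exposure occurring while the
#'   host is in bed.
#' @param f_livestock Fraction of non-human meals taken on treatable
#'   livestock (as opposed to wild or untreatable animals).
#' @param r_indoor_rest Probability of resting indoors after an indoor feed
#'   (drives exposure to residual wall sprays).
#' @param sugar_rate Probability of taking at least one sugar meal per
#'   feeding cycle (drives exposure to toxic sugar baits).
#'
#' @return An object of class `behaviour_profile`: a named list of the six
#'   fractions.
#' @examples
#' p <- behaviour_profile(q_human = 0.5, pi_indoor = 0.9, pi_in_bed = 0.8,
#'                        f_livestock = 0.9, r_indoor_rest = 0.3)
#' attempt_weights(p)
#' @export
behaviour_profile <- function(q_human, pi_indoor, pi_in_bed,
                              f_livestock = 0, r_indoor_rest = 0,
                              sugar_rate = 0) {
  prof <- list(
    q_human       = check_prob(q_human, "q_human"),
    pi_indoor     = check_prob(pi_indoor, "pi_indoor"),
    pi_in_bed     = check_prob(pi_in_bed, "pi_in_bed"),
    f_livestock   = check_prob(f_livestock, "f_livestock"),
    r_indoor_rest = check_prob(r_indoor_rest, "r_indoor_rest"),
    sugar_rate    = check_prob(sugar_rate, "sugar_rate")
  )
  class(prof) <- "behaviour_profile"
  prof
}

#' Baseline attempt weights over the five compartments
#'
#' Decomposes a behaviour profile into the probability that a given
#' blood-feeding attempt, absent any intervention, is directed at each
#' compartment: `q*pi_i*pi_b`, `q*pi_i*(1-pi_b)`, `q*(1-pi_i)`,
#' `(1-q)*f_l` and `(1-q)*(1-f_l)`. The weights are non-negative and sum
#' to one.
#'
#' @param profile A [behaviour_profile()].
#' @return Named numeric vector over [COMPARTMENTS], summing to 1.
#' @export
attempt_weights <- function(profile) {
  stopifnot(inherits(profile, "behaviour_profile"))
  q  <- profile$q_human
  pi <- profile$pi_indoor
  pb <- profile$pi_in_bed
  fl <- profile$f_livestock
  w <- c(
    human_indoor_in_bed     = q * pi * pb,
    human_indoor_out_of_bed = q * pi * (1 - pb),
    human_outdoor           = q * (1 - pi),
    livestock               = (1 - q) * fl,
    other_animal            = (1 - q) * (1 - fl)
  )
  stopifnot(abs(sum(w) - 1) < PROB_TOL)
  w
}

#' @export
print.behaviour_profile <- function(x, ...) {
  cat("<behaviour_profile>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
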