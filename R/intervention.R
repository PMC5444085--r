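#' @rdname intervention
#' @format `INTERVENTION_KINDS` is the character vector of recognised
#'   technology kinds.
#' @export
INTERVENTION_KINDS <- c(
  "LLIN", "IRS", "SCREENING", "EAVE_DEVICE", "TREATED_CLOTHING",
  "EMANATOR", "LIVESTOCK_INSECTICIDE", "SUGAR_BAIT", "SWARM_SPRAY"
)

# default compartments each attack-phase technology protects, and the phase
# each kind acts in: "attack" kinds meet the mosquito before/while it feeds,
# "post" kinds kill it between a successful feed and the next cycle
KIND_PHASE <- c(
  LLIN = "attack", SCREENING = "attack", EAVE_DEVICE = "attack",
  TREATED_CLOTHING = "attack", EMANATOR = "attack",
  IRS = "post", LIVESTOCK_INSECTICIDE = "post",
  SUGAR_BAIT = "post", SWARM_SPRAY = "post"
)

KIND_TARGETS <- list(
  LLIN                  = "human_indoor_in_bed",
  SCREENING             = INDOOR_COMPARTMENTS,
  EAVE_DEVICE           = INDOOR_COMPARTMENTS,
  TREATED_CLOTHING      = "human_outdoor",
  EMANATOR              = "human_outdoor",
  IRS                   = INDOOR_COMPARTMENTS,  # via indoor resting after an indoor feed
  LIVESTOCK_INSECTICIDE = "livestock",
  SUGAR_BAIT            = COMPARTMENTS,         # sugar feeding is compartment-independent
  SWARM_SPRAY           = COMPARTMENTS          # swarm aggregation likewise
)

#' A single vector-control intervention
#'
#' One control technology in a layered stack: which behavioural compartments
#' it acts on, what fraction of the targeted resource it covers, and the
#' per-encounter probabilities of killing the mosquito before it feeds,
#' blocking it non-lethally (diverting it to a fresh attempt) or killing it
#' after a successful feed.
#'
#' Attack-phase kinds (`LLIN`, `SCREENING`, `EAVE_DEVICE`,
#' `TREATED_CLOTHING`, `EMANATOR`) are met during host attack and use
#' `pre_kill` and `block`; their `post_kill`, if non-zero, applies to
#' mosquitoes that fed at a covered resource despite them. Post-phase kinds
#' act between feed and oviposition: `IRS` kills indoor resters after an
#' indoor feed (scaled by the profile's `r_indoor_rest`),
#' `LIVESTOCK_INSECTICIDE` (topical or systemic/endectocide products) kills
#' mosquitoes that fed on covered livestock, `SUGAR_BAIT` kills sugar
#' feeders (scaled by the profile's `sugar_rate`) and `SWARM_SPRAY` applies
#' a per-cycle kill to mosquitoes aggregating in treated swarm sites.
#'
#' @param kind One of `INTERVENTION_KINDS`.
#' @param coverage Fraction of the targeted resource covered in `[0, 1]`
#'   (net usage U_h for LLINs, house coverage C_h for IRS/screening/eave
#'   devices, covered fraction of livestock, etc.).
#' @param pre_kill Probability an attack on a covered resource kills the
#'   mosquito before feeding.
#' @param block Probability such an attack is blocked non-lethally.
#'   `pre_kill + block` must not exceed 1.
#' @param post_kill Probability of death after successfully feeding at (or
#'   resting in) a covered resource.
#' @param targets Compartments the technology acts on; defaults to the
#'   standard set for `kind` and must be a subset of it.
#'
#' @return An object of class `intervention`.
#' @examples
#' llin <- intervention("LLIN", coverage = 0.8, block = 0.625)
#' irs  <- intervention("IRS", coverage = 0.7, post_kill = 0.8)
#' @export
intervention <- function(kind, coverage, pre_kill = 0, block = 0,
                         post_kill = 0, targets = NULL) {
  kind <- match.arg(kind, INTERVENTION_KINDS)
  coverage  <- check_prob(coverage, "coverage")
  pre_kill  <- check_prob(pre_kill, "pre_kill")
  block     <- check_prob(block, "block")
  post_kill <- check_prob(post_kill, "post_kill")
  if (pre_kill + block > 1 + PROB_TOL) {
    stop("pre_kill + block must not exceed 1", call. = FALSE)
  }
  allowed <- KIND_TARGETS[[kind]]
  if (is.null(targets)) {
    targets <- allowed
  } else {
    bad <- setdiff(targets, COMPARTMENTS)
    if (length(bad)) {
      stop("unknown compartment(s) in targets: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (length(setdiff(targets, allowed))) {
      stop(sprintf("targets inconsistent with kind %s (allowed: %s)",
                   kind, paste(allowed, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(kind = kind, coverage = coverage, pre_kill = pre_kill,
         block = block, post_kill = post_kill, targets = targets,
         phase = KIND_PHASE[[kind]]),
    class = "intervention"
  )
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("<intervention> %s  coverage=%.3f pre_kill=%.3f block=%.3f post_kill=%.3f\n",
              x$kind, x$coverage, x$pre_kill, x$block, x$post_kill))
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

as_intervention_list <- function(interventions) {
  if (inherits(interventions, "intervention")) interventions <- list(interventions)
  if (!is.list(interventions) ||
      !all(vapply(interventions, inherits, logical(1), "intervention"))) {
    stop("'interventions' must be a list of intervention objects", call. = FALSE)
  }
  interventions
}
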