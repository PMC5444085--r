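# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic survey generator
#'
#' Bundles the true behavioural parameters, nightly biting-curve shape,
#' human activity schedule, sample sizes and heterogeneity spreads that the
#' generators draw from. Defaults describe a zoophilic, endophagic East
#' African vector scenario: half of baseline meals on humans, 90% of human
#' exposure indoors absent protection, most non-human meals on cattle, a
#' bimodal biting night with late-evening and pre-dawn peaks, and people
#' indoors from 20:00 to 06:00 (in bed 22:00 to 05:00).
#'
#' @param q_human,pi_indoor,pi_in_bed,f_livestock,r_indoor_rest,sugar_rate
#'   True behavioural fractions (see [behaviour_profile()]).
#' @param peak_hours Hours (0-23) of the two biting-activity peaks.
#' @param peak_concentrations Circular (von Mises) concentrations of each
#'   peak; larger is sharper.
#' @param peak_weights Mixture weights of the two peaks (normalised
#'   internally).
#' @param bites_per_night Expected bites per person-night summed over hours.
#' @param indoors_hour,leave_hour Evening hour people go indoors (12-23) and
#'   morning hour they leave the house (1-11); the indoor window wraps
#'   midnight.
#' @param bed_hour,rise_hour In-bed window, contained in the indoor window.
#' @param person_nights Person-nights of biting-catch effort per survey.
#' @param blood_meals Number of blood meals host-identified per survey.
#' @param site_concentration Beta concentration governing between-site
#'   spread of behavioural fractions: small values (default 0.3) span nearly
#'   the whole `[0, 1]` range, `Inf` makes all sites identical.
#' @param rest_median,rest_sdlog Median and log-scale SD of the between-site
#'   distribution of the indoor-resting parameter (log-normal, capped at 1);
#'   `rest_sdlog = 1` spans several-hundred-fold ranges over ~1000 sites.
#' @param noise `"poisson"` for counting noise on biting catches, `"none"`
#'   for expected values (noiseless limit).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(q_human = 0.5, pi_indoor = 0.9, pi_in_bed = 0.75,
                         f_livestock = 0.9, r_indoor_rest = 0.05,
                         sugar_rate = 0.2,
                         peak_hours = c(21, 4), peak_concentrations = c(2, 2),
                         peak_weights = c(0.6, 0.4), bites_per_night = 10,
                         indoors_hour = 20, leave_hour = 6,
                         bed_hour = 22, rise_hour = 5,
                         person_nights = 500, blood_meals = 200,
                         site_concentration = 0.3,
                         rest_median = 0.05, rest_sdlog = 1,
                         noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  for (nm in c("q_human", "pi_indoor", "pi_in_bed", "f_livestock",
               "r_indoor_rest", "sugar_rate")) {
    check_prob(get(nm), nm)
  }
  stopifnot(length(peak_hours) == 2, all(peak_hours >= 0 & peak_hours < 24),
            length(peak_concentrations) == 2, all(peak_concentrations > 0),
            length(peak_weights) == 2, all(peak_weights > 0),
            bites_per_night > 0, person_nights > 0)
  if (!(indoors_hour %in% 12:23)) {
    stop("indoors_hour must be an evening hour (12-23)", call. = FALSE)
  }
  if (!(leave_hour %in% 1:11)) {
    stop("leave_hour must be a morning hour (1-11); the indoor window wraps midnight",
         call. = FALSE)
  }
  if (!(bed_hour %in% indoors_hour:23) || !(rise_hour %in% 1:leave_hour)) {
    stop("in-bed window (bed_hour, rise_hour) must lie inside the indoor window",
         call. = FALSE)
  }
  if (is.na(site_concentration) || site_concentration <= 0) {
    stop("degenerate spread: site_concentration must be positive (Inf for no spread)",
         call. = FALSE)
  }
  if (is.na(rest_sdlog) || rest_sdlog < 0 || rest_median <= 0 || rest_median > 1) {
    stop("degenerate spread: rest_median must be in (0, 1] and rest_sdlog >= 0",
         call. = FALSE)
  }
  structure(list(
    q_human = q_human, pi_indoor = pi_indoor, pi_in_bed = pi_in_bed,
    f_livestock = f_livestock, r_indoor_rest = r_indoor_rest,
    sugar_rate = sugar_rate, peak_hours = peak_hours,
    peak_concentrations = peak_concentrations, peak_weights = peak_weights,
    bites_per_night = bites_per_night, indoors_hour = indoors_hour,
    leave_hour = leave_hour, bed_hour = bed_hour, rise_hour = rise_hour,
    person_nights = person_nights, blood_meals = blood_meals,
    site_concentration = site_concentration, rest_median = rest_median,
    rest_sdlog = rest_sdlog, noise = noise, seed = as.integer(seed)
  ), class = "synth_config")
}

# indicator of being in a possibly midnight-wrapping hour window [from, to)
in_window <- function(hour, from, to) {
  as.numeric(hour >= from | hour < to)
}

# discretised two-peak circular-normal biting activity, normalised to sum 1
biting_curve <- function(config) {
  h <- 0:23
  dens <- function(mu, kappa) exp(kappa * cos(2 * pi * (h - mu) / 24))
  wts <- config$peak_weights / sum(config$peak_weights)
  mix <- wts[1] * dens(config$peak_hours[1], config$peak_concentrations[1]) +
         wts[2] * dens(config$peak_hours[2], config$peak_concentrations[2])
  mix / sum(mix)
}

# expected hourly biting rates (per person-hour) whose exposure-weighted
# indoor share equals the configured pi_indoor exactly
expected_rates <- function(config) {
  lambda <- biting_curve(config)
  h_in <- in_window(0:23, config$indoors_hour, config$leave_hour)
  h_bed <- in_window(0:23, config$bed_hour, config$rise_hour)
  A <- sum(lambda * h_in)
  C <- sum(lambda * (1 - h_in))
  pi_i <- config$pi_indoor
  if (pi_i >= 1) {
    rho_in <- 1; rho_out <- 0
  } else if (pi_i <= 0) {
    rho_in <- 0; rho_out <- 1
  } else {
    rho_out <- 1
    rho_in <- pi_i * C / ((1 - pi_i) * A)
  }
  b_in <- lambda * rho_in
  b_out <- lambda * rho_out
  exposure <- sum(b_in * h_in + b_out * (1 - h_in))
  scale <- config$bites_per_night / exposure
  data.frame(hour = 0:23,
             bite_rate_indoor = b_in * scale,
             bite_rate_outdoor = b_out * scale,
             frac_humans_indoor = h_in,
             frac_humans_in_bed = h_bed)
}

#' Generate a synthetic hourly biting survey
#'
#' Emulates a 24-hour human-landing/trap survey: expected indoor and outdoor
#' biting rates follow the configured bimodal nightly activity curve, split
#' between locations so that the exposure-weighted indoor fraction equals
#' the configured true `pi_indoor`; observed catches add Poisson counting
#' noise at the configured person-nights of effort (or none, in the
#' noiseless limit). Output is deterministic under a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return Survey data frame in the schema of [exposure_distribution()].
#' @export
gen_biting_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  exp_rates <- expected_rates(config)
  if (config$noise == "none") return(exp_rates)
  with_seed(seed, {
    pn <- config$person_nights
    exp_rates$bite_rate_indoor <-
      stats::rpois(24, pn * exp_rates$bite_rate_indoor) / pn
    exp_rates$bite_rate_outdoor <-
      stats::rpois(24, pn * exp_rates$bite_rate_outdoor) / pn
    exp_rates
  })
}

#' Generate synthetic blood-meal host counts
#'
#' Multinomial draws over `{human, cattle, other}` with probabilities
#' implied by the true human blood index and livestock share:
#' `(q, (1-q)*f_l, (1-q)*(1-f_l))`.
#'
#' @param config A [synth_config()].
#' @param n Number of blood meals (defaults to `config$blood_meals`).
#' @param seed Optional seed override.
#' @return Named integer vector of counts by host class.
#' @export
gen_bloodmeals <- function(config, n = config$blood_meals, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (is.na(n) || n <= 0) stop("number of blood meals must be positive",
                               call. = FALSE)
  q <- config$q_human
  fl <- config$f_livestock
  probs <- c(human = q, cattle = (1 - q) * fl, other = (1 - q) * (1 - fl))
  with_seed(seed, {
    draw <- stats::rmultinom(1, size = n, prob = probs)[, 1]
    stats::setNames(as.integer(draw), names(probs))
  })
}

#' Generate a heterogeneous ensemble of site-level behaviour profiles
#'
#' Emulates between-site behavioural heterogeneity: behavioural fractions
#' drawn from Beta distributions centred on the configured truths with
#' concentration `site_concentration` (small values span nearly the full
#' `[0, 1]` range, `Inf` gives identical sites), and the indoor-resting
#' parameter drawn log-normally so that its range across many sites can
#' exceed several hundred-fold.
#'
#' @param config A [synth_config()].
#' @param n_sites Number of sites (`>= 1`).
#' @param seed Optional seed override.
#' @return List of `n_sites` [behaviour_profile()] objects.
#' @export
gen_site_ensemble <- function(config, n_sites, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (is.na(n_sites) || n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  kappa <- config$site_concentration
  draw_frac <- function(mean) {
    if (is.infinite(kappa)) return(rep(mean, n_sites))
    if (mean <= 0 || mean >= 1) return(rep(mean, n_sites))
    stats::rbeta(n_sites, mean * kappa, (1 - mean) * kappa)
  }
  with_seed(seed, {
    q  <- draw_frac(config$q_human)
    pi <- draw_frac(config$pi_indoor)
    pb <- draw_frac(config$pi_in_bed)
    fl <- draw_frac(config$f_livestock)
    rr <- if (config$rest_sdlog == 0) {
      rep(config$rest_median, n_sites)
    } else {
      pmin(1, stats::rlnorm(n_sites, log(config$rest_median), config$rest_sdlog))
    }
    lapply(seq_len(n_sites), function(i) {
      behaviour_profile(q[i], pi[i], pb[i], fl[i], rr[i], config$sugar_rate)
    })
  })
}

#' True behaviour profile of a synthetic configuration
#'
#' @param config A [synth_config()].
#' @return The [behaviour_profile()] whose parameters the generators draw
#'   around.
#' @export
true_profile <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  behaviour_profile(config$q_human, config$pi_indoor, config$pi_in_bed,
                    config$f_livestock, config$r_indoor_rest,
                    config$sugar_rate)
}
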