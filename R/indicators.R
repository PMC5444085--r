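# Wilson score interval for a binomial proportion; x may be fractional when
# mixed blood meals are counted partially toward each host class
wilson_interval <- function(x, n, conf = 0.95) {
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  if (conf <= 0 || conf >= 1) stop("'conf' must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = if (x <= 0) 0 else max(0, centre - half),
    upper = if (x >= n) 1 else min(1, centre + half))
}

new_proportion_estimate <- function(estimate, interval, conf, n, note = NULL) {
  structure(list(estimate = estimate, lower = unname(interval[1]),
                 upper = unname(interval[2]), conf = conf, n = n, note = note),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%.4f  [%.0f%% score CI %.4f, %.4f]  n=%.1f\n",
              x$estimate, 100 * x$conf, x$lower, x$upper, x$n))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Human blood index from blood-meal host counts
#'
#' Estimates the human blood index — the fraction of a vector population's
#' blood meals obtained from humans — from host-identified blood-meal counts,
#' with a Wilson score confidence interval (well behaved at the 0 and 1
#' boundaries common in small entomological samples). Mixed meals recorded
#' under a `+`-joined host name (e.g. `"human+cattle"`) are split across
#' their component hosts with weight `mixed_weight` on the human component.
#'
#' @param counts Named non-negative numeric vector of blood-meal counts by
#'   host class; the human class must be named `"human"`.
#' @param conf Confidence level, in `(0, 1)`.
#' @param mixed_weight Weight given to the human component of a mixed
#'   human-plus-animal meal (default 0.5, an even split).
#' @return A `proportion_estimate` with fields `estimate`, `lower`, `upper`,
#'   `conf`, `n`.
#' @examples
#' human_blood_index(c(human = 30, cattle = 10))
#' @export
human_blood_index <- function(counts, conf = 0.95, mixed_weight = 0.5) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("'counts' must be a named vector of host counts", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  mixed_weight <- check_prob(mixed_weight, "mixed_weight")
  n <- sum(counts)
  if (n <= 0) stop("total blood-meal count must be positive", call. = FALSE)
  human <- 0
  for (nm in names(counts)) {
    hosts <- strsplit(nm, "+", fixed = TRUE)[[1]]
    if (identical(hosts, "human")) {
      human <- human + counts[[nm]]
    } else if ("human" %in% hosts) {
      human <- human + mixed_weight * counts[[nm]]
    }
  }
  new_proportion_estimate(human / n, wilson_interval(human, n, conf), conf, n)
}

#' Indoor-resting fraction from resting collections
#'
#' Simple proportion of blood-fed mosquitoes collected resting indoors versus
#' outdoors, with a Wilson score interval. This is a collection-based
#' approximation of the per-feeding-cycle indoor resting-site usage rate
#' estimated by mark-and-model methods in the primary literature; the output
#' carries a note flagging the approximation.
#'
#' @param indoor_fed_count,outdoor_fed_count Non-negative integer counts of
#'   fed mosquitoes collected resting indoors / outdoors.
#' @param conf Confidence level.
#' @return A `proportion_estimate`.
#' @export
indoor_resting_fraction <- function(indoor_fed_count, outdoor_fed_count,
                                    conf = 0.95) {
  indoor_fed_count <- unname(as.numeric(indoor_fed_count))
  outdoor_fed_count <- unname(as.numeric(outdoor_fed_count))
  if (indoor_fed_count < 0 || outdoor_fed_count < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- indoor_fed_count + outdoor_fed_count
  if (n <= 0) stop("total resting count must be positive", call. = FALSE)
  new_proportion_estimate(
    indoor_fed_count / n, wilson_interval(indoor_fed_count, n, conf), conf, n,
    note = "collection proportion; approximates the per-cycle indoor resting-site usage rate"
  )
}

validate_survey <- function(survey) {
  needed <- c("hour", "bite_rate_indoor", "bite_rate_outdoor",
              "frac_humans_indoor", "frac_humans_in_bed")
  if (!is.data.frame(survey) || !all(needed %in% names(survey))) {
    stop("survey must be a data frame with columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(survey) != 24 || !setequal(survey$hour, 0:23)) {
    stop("survey must have 24 rows, one per hour 0-23", call. = FALSE)
  }
  survey <- survey[order(survey$hour), , drop = FALSE]
  if (any(survey$bite_rate_indoor < 0) || any(survey$bite_rate_outdoor < 0)) {
    stop("biting rates must be non-negative", call. = FALSE)
  }
  check_prob(survey$frac_humans_indoor, "frac_humans_indoor", len = 24L)
  check_prob(survey$frac_humans_in_bed, "frac_humans_in_bed", len = 24L)
  if (any(survey$frac_humans_in_bed > survey$frac_humans_indoor + PROB_TOL)) {
    stop("frac_humans_in_bed cannot exceed frac_humans_indoor", call. = FALSE)
  }
  survey
}

#' Where and when humans are actually exposed to bites
#'
#' Weights hourly indoor and outdoor biting rates by the fraction of humans
#' actually indoors (and in bed) at each hour, turning raw vector biting
#' curves into the distribution of human exposure:
#' `w_in(t) = B_in(t) * H_in(t)`, `w_out(t) = B_out(t) * (1 - H_in(t))`.
#' Returns the indoor exposure fraction
#' `pi_indoor = sum(w_in) / sum(w_in + w_out)`, the in-bed fraction of
#' indoor exposure (weighting by the in-bed time budget), and the full
#' hourly exposure profile.
#'
#' @param survey Data frame with columns `hour` (0-23), `bite_rate_indoor`,
#'   `bite_rate_outdoor` (bites per person-hour), `frac_humans_indoor`,
#'   `frac_humans_in_bed` (per-hour time budgets). Hour bins are half-open
#'   `[h, h+1)`.
#' @param net_users_protected_in_bed If `TRUE`, indoor exposure while in bed
#'   is excluded (the residual exposure distribution of a fully protected
#'   net user); default `FALSE` measures unprotected exposure.
#' @return List with `pi_indoor`, `pi_in_bed`, and `hourly` (data frame:
#'   hour, w_indoor, w_outdoor).
#' @examples
#' sv <- data.frame(hour = 0:23, bite_rate_indoor = 1, bite_rate_outdoor = 1,
#'                  frac_humans_indoor = 0.5, frac_humans_in_bed = 0.25)
#' exposure_distribution(sv)$pi_indoor  # 0.5 by symmetry
#' @export
exposure_distribution <- function(survey, net_users_protected_in_bed = FALSE) {
  survey <- validate_survey(survey)
  h_in <- if (net_users_protected_in_bed) {
    survey$frac_humans_indoor - survey$frac_humans_in_bed
  } else {
    survey$frac_humans_indoor
  }
  w_in <- survey$bite_rate_indoor * h_in
  w_out <- survey$bite_rate_outdoor * (1 - survey$frac_humans_indoor)
  total <- sum(w_in) + sum(w_out)
  if (total <= 0) stop("all-zero exposure: no bites overlap human presence",
                       call. = FALSE)
  w_bed <- survey$bite_rate_indoor * survey$frac_humans_in_bed
  pi_in_bed <- if (net_users_protected_in_bed) {
    0
  } else if (sum(w_in) > 0) sum(w_bed) / sum(w_in) else 0
  list(
    pi_indoor = sum(w_in) / total,
    pi_in_bed = pi_in_bed,
    hourly = data.frame(hour = survey$hour, w_indoor = w_in, w_outdoor = w_out)
  )
}

#' Outdoor fraction of residual exposure under house screening
#'
#' When houses are screened with protective efficacy `screening_efficacy`,
#' indoor exposure is discounted by the screening and the remaining
#' (residual) exposure redistributes toward outdoors:
#' `sum(w_out) / (sum(w_out) + (1 - efficacy) * sum(w_in))`. At efficacy 0
#' this is the plain outdoor exposure fraction; at efficacy 1 all residual
#' exposure is outdoors.
#'
#' @inheritParams exposure_distribution
#' @param screening_efficacy Protective efficacy of the screening in
#'   `[0, 1]` (0.9 for well-screened houses).
#' @return Fraction of residual exposure occurring outdoors.
#' @export
residual_outdoor_fraction <- function(survey, screening_efficacy) {
  screening_efficacy <- check_prob(screening_efficacy, "screening_efficacy")
  ed <- exposure_distribution(survey)
  w_in <- sum(ed$hourly$w_indoor)
  w_out <- sum(ed$hourly$w_outdoor)
  denom <- w_out + (1 - screening_efficacy) * w_in
  if (denom <= 0) {
    stop("no residual exposure: outdoor exposure is zero and screening is total",
         call. = FALSE)
  }
  w_out / denom
}

#' Read an hourly biting survey CSV
#'
#' Expects the fixed schema `hour, bite_rate_indoor, bite_rate_outdoor,
#' frac_humans_indoor, frac_humans_in_bed` with a header row, 24 rows (one
#' per hour 0-23).
#'
#' @param path Path to the CSV file.
#' @return Validated survey data frame.
#' @export
read_biting_survey <- function(path) {
  validate_survey(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read blood-meal host counts from CSV
#'
#' Expects columns `host, count` with a header row.
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector of counts by host.
#' @export
read_bloodmeals <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("host", "count") %in% names(d))) {
    stop("bloodmeals CSV must have columns: host, count", call. = FALSE)
  }
  stats::setNames(as.numeric(d$count), d$host)
}

#' Read resting-collection counts from CSV
#'
#' Expects columns `location, fed_count` with locations `indoor` and
#' `outdoor`.
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector with elements `indoor` and `outdoor`.
#' @export
read_resting <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("location", "fed_count") %in% names(d))) {
    stop("resting CSV must have columns: location, fed_count", call. = FALSE)
  }
  out <- stats::setNames(as.numeric(d$fed_count), d$location)
  if (!all(c("indoor", "outdoor") %in% names(out))) {
    stop("resting CSV must contain 'indoor' and 'outdoor' rows", call. = FALSE)
  }
  out[c("indoor", "outdoor")]
}
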