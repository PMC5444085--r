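vc_validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("vc_validation_error", "error")))
}

# strict key check: unknown keys are rejected with the path to the offender
check_keys <- function(x, allowed, required, path) {
  if (!is.list(x)) vc_validation_error(sprintf("'%s' must be a mapping", path))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    vc_validation_error(sprintf("unknown key '%s.%s'", path, unknown[1]))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    vc_validation_error(sprintf("missing required key '%s.%s'", path, missing[1]))
  }
  invisible(x)
}

check_cfg_prob <- function(x, path) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    vc_validation_error(sprintf("'%s' must be a number in [0, 1]", path))
  }
  x
}

#' Read and validate a scenario configuration file
#'
#' A scenario file (YAML or JSON) describes a vector population's behaviour
#' profile, an ordered stack of interventions and, optionally, synthetic
#' survey settings and human-context flags:
#' \preformatted{
#' profile:
#'   q_human: 0.5
#'   pi_indoor: 0.9
#'   pi_in_bed: 0.8
#'   f_livestock: 0.9
#'   r_indoor_rest: 0.3
#' interventions:
#'   - {kind: LLIN, coverage: 0.8, block: 0.625}
#'   - {kind: LIVESTOCK_INSECTICIDE, coverage: 0.6, post_kill: 0.8}
#' }
#' Validation is strict: unknown keys and out-of-range values are rejected
#' with an error naming the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return List with `profile` (a [behaviour_profile()]), `interventions`
#'   (list of [intervention()]), `baseline_survival`, and optional `synth`
#'   (a [synth_config()]) and `context` (named logical flags).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) vc_validation_error(paste("config file not found:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, c("profile", "interventions", "synth", "context",
                    "baseline_survival"),
             "profile", "scenario")

  pf <- raw$profile
  check_keys(pf, c("q_human", "pi_indoor", "pi_in_bed", "f_livestock",
                   "r_indoor_rest", "sugar_rate"),
             c("q_human", "pi_indoor", "pi_in_bed"), "profile")
  for (nm in names(pf)) check_cfg_prob(pf[[nm]], paste0("profile.", nm))
  profile <- do.call(behaviour_profile, pf)

  interventions <- list()
  if (!is.null(raw$interventions)) {
    if (!is.list(raw$interventions)) {
      vc_validation_error("'interventions' must be a sequence")
    }
    interventions <- lapply(seq_along(raw$interventions), function(i) {
      iv <- raw$interventions[[i]]
      ipath <- sprintf("interventions[%d]", i)
      check_keys(iv, c("kind", "coverage", "pre_kill", "block", "post_kill",
                       "targets"),
                 c("kind", "coverage"), ipath)
      if (!is.character(iv$kind) || !(iv$kind %in% INTERVENTION_KINDS)) {
        vc_validation_error(sprintf("'%s.kind' must be one of: %s", ipath,
                                    paste(INTERVENTION_KINDS, collapse = ", ")))
      }
      for (nm in intersect(names(iv), c("coverage", "pre_kill", "block",
                                        "post_kill"))) {
        check_cfg_prob(iv[[nm]], paste0(ipath, ".", nm))
      }
      tryCatch(do.call(intervention, iv),
               error = function(e) vc_validation_error(
                 sprintf("%s: %s", ipath, conditionMessage(e))))
    })
  }

  synth <- NULL
  if (!is.null(raw$synth)) {
    check_keys(raw$synth,
               c("seed", "person_nights", "blood_meals", "noise",
                 "bites_per_night", "peak_hours", "peak_concentrations",
                 "peak_weights", "indoors_hour", "leave_hour", "bed_hour",
                 "rise_hour", "site_concentration", "rest_median",
                 "rest_sdlog"),
               character(0), "synth")
    args <- c(pf[intersect(names(pf), c("q_human", "pi_indoor", "pi_in_bed",
                                        "f_livestock", "r_indoor_rest",
                                        "sugar_rate"))],
              raw$synth)
    synth <- tryCatch(do.call(synth_config, args),
                      error = function(e) vc_validation_error(
                        sprintf("synth: %s", conditionMessage(e))))
  }

  context <- list(sleeps_indoors = FALSE, migrant_shelters = FALSE,
                  outdoor_night_activity = FALSE, owns_livestock = FALSE,
                  sugar_labelling_positive = FALSE,
                  swarm_labelling_positive = FALSE)
  if (!is.null(raw$context)) {
    check_keys(raw$context, names(context), character(0), "context")
    for (nm in names(raw$context)) {
      if (!is.logical(raw$context[[nm]]) || is.na(raw$context[[nm]])) {
        vc_validation_error(sprintf("'context.%s' must be true/false", nm))
      }
      context[[nm]] <- raw$context[[nm]]
    }
  }

  baseline_survival <- raw$baseline_survival %||% 0.7
  check_cfg_prob(baseline_survival, "baseline_survival")

  list(profile = profile, interventions = interventions, synth = synth,
       context = context, baseline_survival = baseline_survival)
}

# recursive sweep: every field whose name marks it as a probability must lie
# in [0, 1] in any written report
assert_prob_fields <- function(x, path = "") {
  prob_pat <- "^(p_|pi_|c_m|q_human|f_livestock|coverage|S_cycle|residual_share)"
  if (is.list(x)) {
    for (nm in names(x)) {
      assert_prob_fields(x[[nm]], paste0(path, ".", nm))
    }
  } else if (is.numeric(x) && grepl(prob_pat, sub("^.*\\.", "", path))) {
    bad <- x[!is.na(x) & (x < -PROB_TOL | x > 1 + PROB_TOL)]
    if (length(bad)) {
      stop(sprintf("internal error: probability field '%s' outside [0, 1]", path),
           call. = FALSE)
    }
  }
  invisible(x)
}

write_report_json <- function(x, path) {
  assert_prob_fields(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}

#' Serialise a cycle outcome as a JSON report
#'
#' Writes all fate probabilities at full double precision.
#'
#' @param outcome A `cycle_outcome` from [single_cycle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycle_report <- function(outcome, path) {
  stopifnot(inherits(outcome, "cycle_outcome"))
  rpt <- list(
    p_pre_death = outcome$p_pre_death,
    p_fed = as.list(outcome$p_fed),
    p_post_death = outcome$p_post_death,
    p_cycle_survival = outcome$p_cycle_survival,
    e_expected = outcome$e_expected,
    c_m = as.list(outcome$c_m)
  )
  invisible(write_report_json(rpt, path))
}

#' Run the full analysis pipeline from a scenario configuration
#'
#' Executes, as configured: synthetic survey generation, indicator
#' estimation, technology recommendation and intervention-stack simulation,
#' writing `survey.csv`, `bloodmeals.csv`, `indicators.json`,
#' `recommendations.json`, `trace.json`, `trace.csv` and a run `manifest.json`
#' into `outdir`. Reruns with an identical configuration and seed produce
#' identical result files. On any failure, files written by the failed run
#' are removed before the error propagates.
#'
#' @param config_path Path to a scenario file (see
#'   [read_scenario_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the configured seed.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config_path, outdir, seed = NULL) {
  cfg <- read_scenario_config(config_path)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(outdir, name)
    written <<- c(written, p)
    p
  }
  withCallingHandlers({
    if (!is.null(cfg$synth)) {
      if (!is.null(seed)) cfg$synth$seed <- as.integer(seed)
      survey <- gen_biting_survey(cfg$synth)
      meals <- gen_bloodmeals(cfg$synth)
      utils::write.csv(survey, out("survey.csv"), row.names = FALSE)
      utils::write.csv(data.frame(host = names(meals), count = as.integer(meals)),
                       out("bloodmeals.csv"), row.names = FALSE)
      ed <- exposure_distribution(survey)
      hbi <- human_blood_index(meals)
      f_liv <- meals[["cattle"]] / sum(meals)
      indicators <- list(
        pi_indoor = ed$pi_indoor, pi_in_bed = ed$pi_in_bed,
        q_human = hbi$estimate, q_human_lower = hbi$lower,
        q_human_upper = hbi$upper, f_livestock_meals = f_liv,
        n_blood_meals = sum(meals), seed = cfg$synth$seed
      )
    } else {
      w <- attempt_weights(cfg$profile)
      indicators <- list(
        pi_indoor = cfg$profile$pi_indoor, pi_in_bed = cfg$profile$pi_in_bed,
        q_human = cfg$profile$q_human,
        f_livestock_meals = unname(w[["livestock"]]),
        n_blood_meals = NA, seed = NA
      )
    }
    write_report_json(indicators, out("indicators.json"))

    ip <- indicator_profile(
      pi_indoor_exposure = indicators$pi_indoor,
      q_human = indicators$q_human,
      f_livestock_meals = indicators$f_livestock_meals,
      sugar_labelling_positive = cfg$context$sugar_labelling_positive,
      swarm_labelling_positive = cfg$context$swarm_labelling_positive,
      sleeps_indoors = cfg$context$sleeps_indoors,
      migrant_shelters = cfg$context$migrant_shelters,
      outdoor_night_activity = cfg$context$outdoor_night_activity,
      owns_livestock = cfg$context$owns_livestock
    )
    recs <- recommend(ip)
    write_report_json(
      lapply(seq_len(nrow(recs)), function(i) as.list(recs[i, ])),
      out("recommendations.json"))

    trace <- apply_stack(cfg$profile, cfg$interventions,
                         baseline_survival = cfg$baseline_survival)
    write_report_json(list(
      summary = lapply(seq_len(nrow(trace$summary)),
                       function(i) as.list(trace$summary[i, ])),
      residual = lapply(seq_len(nrow(trace$residual)),
                        function(i) as.list(trace$residual[i, ]))
    ), out("trace.json"))
    utils::write.csv(trace_to_df(trace), out("trace.csv"), row.names = FALSE)

    manifest <- list(
      tool = "vectorcycle",
      version = as.character(utils::packageVersion("vectorcycle")),
      config = normalizePath(config_path),
      config_md5 = unname(tools::md5sum(config_path)),
      seed = if (!is.null(cfg$synth)) cfg$synth$seed else seed,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      outputs = basename(written)
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
  })
}
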