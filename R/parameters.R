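#' Default model parameters
#'
#' The complete parameter bundle for the screening-pathway model: test
#' performance of the combined test at each risk cut-off and of the quadruple
#' test, NIPT and invasive-test characteristics, weekly fetal-loss hazards,
#' uptake rates, unit costs (2011/12 GBP) and event-week timing. All
#' percentages are stored as proportions in `[0, 1]`; costs are pounds.
#'
#' Key values: screening uptake 69% with 15% late arrivals screened in the
#' second trimester; invasive uptake 80% (unaffected) / 90% (DS-affected),
#' reused for contingent NIPT uptake; first-line NIPT uptake 69%; NIPT
#' detection rate 99%, false-positive rate 1%, sample failure 5% (one repeat,
#' full cost) and no procedural loss; invasive tests detect every DS case,
#' cost GBP 479 and carry a 0.5% procedure-related miscarriage risk; TOP
#' uptake 92.1%; births split 75.2% vaginal / 24.8% caesarean.
#'
#' The weekly spontaneous fetal-loss hazard is piecewise constant: unaffected
#' pregnancies 0.0012 (weeks 10-25) and 0.00034 (weeks 26-40); DS-affected
#' pregnancies 0.07067 (weeks 10-15) and 0.0051 (weeks 16-40).
#'
#' Two defaults are the package's own calibration rather than published unit
#' values: `costs$repeat_nt` (GBP 6.50 per repeat nuchal-translucency
#' measurement; the source programme costs include repeat NT but print no unit
#' cost) and `prevalence$week10_cohort_prevalence` (2.95 per 1,000 pregnancies
#' DS-affected at week 10, from national register early-pregnancy estimates).
#'
#' @return A validated parameter bundle of class `nipt_params` (a named,
#'   nested list; see [load_parameters()] for the file representation).
#' @seealso [load_parameters()], [scenario_presets()], [write_parameters()]
#' @examples
#' p <- default_parameters()
#' p$nipt$detection_rate
#' p$costs$invasive_test
#' @export
default_parameters <- function() {
  params <- list(
    cohort_size = 10000,
    screening = list(
      combined = list(
        `150`  = list(detection_rate = 0.85, false_positive_rate = 0.025),
        `500`  = list(detection_rate = 0.94, false_positive_rate = 0.07),
        `1000` = list(detection_rate = 0.96, false_positive_rate = 0.12),
        `2000` = list(detection_rate = 0.98, false_positive_rate = 0.19)
      ),
      quadruple = list(detection_rate = 0.805, false_positive_rate = 0.04),
      # NT measurement failure 14-19% by gestational week, interpolated
      # linearly across the combined-test window
      nt_failure = list(first_week = 11, last_week = 14,
                        first_rate = 0.14, last_rate = 0.19)
    ),
    invasive = list(
      cvs = list(detection_rate = 1.0, sample_failure_rate = 0.013,
                 procedure_miscarriage_rate = 0.005),
      amniocentesis = list(detection_rate = 1.0, sample_failure_rate = 0.008,
                           procedure_miscarriage_rate = 0.005)
    ),
    nipt = list(detection_rate = 0.99, false_positive_rate = 0.01,
                sample_failure_rate = 0.05, procedure_miscarriage_rate = 0.0),
    loss_rates = list(
      unaffected = list(weeks_10_25 = 0.0012, weeks_26_40 = 0.00034),
      affected   = list(weeks_10_15 = 0.07067, weeks_16_40 = 0.0051)
    ),
    uptakes = list(
      screening = 0.69,
      late_arrival = 0.15,
      invasive_unaffected = 0.80,
      invasive_affected = 0.90,
      nipt_unaffected = 0.80,
      nipt_affected = 0.90,
      nipt_firstline = 0.69,
      top = 0.921
    ),
    birth_mode = list(vaginal = 0.752, caesarean = 0.248),
    costs = list(
      combined_test = 27,
      quadruple_test = 35,
      invasive_test = 479,
      fetal_loss = 511,
      top_first_trimester = 697,
      top_second_trimester = 882,
      vaginal_birth = 1341,
      caesarean_birth = 2436,
      nipt_test = 500,
      blood_draw = 3,
      repeat_nt = 6.5
    ),
    timing = list(
      combined_screen = 12,
      cvs = 13,
      quadruple_screen = 16,
      amniocentesis = 17,
      contingent_nipt_t1 = 13,
      contingent_invasive_t1 = 14,
      contingent_nipt_t2 = 17,
      contingent_invasive_t2 = 18,
      firstline_nipt = 11,
      firstline_invasive = 12,
      first_trimester_max_week = 14
    ),
    prevalence = list(week10_cohort_prevalence = 0.00295)
  )
  structure(validate_parameters(params), class = "nipt_params")
}

#' Load and validate a parameter configuration
#'
#' Reads a YAML (or JSON, which YAML subsumes) document whose keys mirror
#' [default_parameters()]; any key left unspecified takes its default.
#' Unknown keys are rejected so that a typo cannot silently corrupt a
#' scenario comparison, and every probability-typed field is checked against
#' `[0, 1]` and every cost against non-negativity, with the offending key
#' path named in the error.
#'
#' @param config_source Path to a YAML/JSON file, a YAML string, a named list
#'   of overrides, or `NULL`/empty for all defaults.
#' @return A validated `nipt_params` bundle.
#' @examples
#' load_parameters(list(uptakes = list(screening = 0.79)))$uptakes$screening
#' @export
load_parameters <- function(config_source = NULL) {
  overrides <-
    if (is.null(config_source)) {
      list()
    } else if (is.list(config_source)) {
      config_source
    } else if (is.character(config_source) && length(config_source) == 1) {
      parsed <- if (file.exists(config_source)) {
        yaml::read_yaml(config_source)
      } else {
        yaml::yaml.load(config_source)
      }
      parsed %||% list()
    } else {
      abort("`config_source` must be a file path, YAML text, a list, or NULL.")
    }
  defaults <- unclass(default_parameters())
  merged <- merge_strict(defaults, overrides, path = character())
  structure(validate_parameters(merged), class = "nipt_params")
}

#' Serialise a parameter bundle to YAML
#'
#' Writing then re-reading with [load_parameters()] round-trips to an equal
#' bundle.
#'
#' @param params A `nipt_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "nipt_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Uptake-scenario presets
#'
#' The published analysis varies the base-case uptakes in three alternative
#' scenarios. `scenario_presets()` returns, for a scenario name, the
#' parameter overrides plus a matching [strategy_spec()]:
#'
#' * `"base_contingent"` (alias `"base"`): contingent NIPT uptake equal to
#'   invasive uptake (80% unaffected / 90% affected).
#' * `"nipt_100"`: contingent NIPT uptake 100%.
#' * `"nipt_100_screen_79"`: contingent NIPT uptake 100% and screening uptake
#'   raised from 69% to 79%.
#' * `"firstline_79"`: first-line NIPT uptake raised from 69% to 79%.
#'
#' @param name Scenario identifier.
#' @return A list with elements `overrides` (a nested list understood by
#'   [load_parameters()]) and `spec` (a `strategy_spec`).
#' @examples
#' scenario_presets("nipt_100_screen_79")$overrides
#' @export
scenario_presets <- function(name) {
  switch(name,
    base = ,
    base_contingent = list(
      overrides = list(),
      spec = strategy_spec("contingent_nipt", cutoff = 150,
                           uptake_scenario = "base")
    ),
    nipt_100 = list(
      overrides = list(uptakes = list(nipt_unaffected = 1.0,
                                      nipt_affected = 1.0)),
      spec = strategy_spec("contingent_nipt", cutoff = 150,
                           uptake_scenario = "nipt_100")
    ),
    nipt_100_screen_79 = list(
      overrides = list(uptakes = list(nipt_unaffected = 1.0,
                                      nipt_affected = 1.0,
                                      screening = 0.79)),
      spec = strategy_spec("contingent_nipt", cutoff = 150,
                           uptake_scenario = "nipt_100_screen_79")
    ),
    firstline_79 = list(
      overrides = list(uptakes = list(nipt_firstline = 0.79)),
      spec = strategy_spec("firstline_nipt", uptake_scenario = "firstline_79")
    ),
    abort(paste0("Unknown scenario name: '", name, "'. Valid names: ",
                 "base_contingent, nipt_100, nipt_100_screen_79, firstline_79."))
  )
}

#' Specify a testing strategy
#'
#' @param strategy One of `"current"`, `"contingent_nipt"`,
#'   `"firstline_nipt"`.
#' @param cutoff Screening risk cut-off denominator (1 in `cutoff`); one of
#'   150, 500, 1000, 2000. Ignored for first-line NIPT.
#' @param uptake_scenario Label recording which uptake scenario the run
#'   belongs to (see [scenario_presets()]); informational.
#' @param include_pregnancy_outcome_costs Add spontaneous-loss, TOP and birth
#'   costs to the cost summary.
#' @param separate_nipt_blood_draw Charge an additional GBP 3 blood draw per
#'   NIPT taker (samples otherwise assumed drawn with the screening sample).
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(strategy = c("current", "contingent_nipt",
                                       "firstline_nipt"),
                          cutoff = 150,
                          uptake_scenario = "base",
                          include_pregnancy_outcome_costs = FALSE,
                          separate_nipt_blood_draw = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy != "firstline_nipt") {
    if (!cutoff %in% c(150, 500, 1000, 2000)) {
      abort(paste0("Unknown screening risk cut-off: ", cutoff,
                   " (valid: 150, 500, 1000, 2000)."))
    }
  }
  structure(
    list(strategy = strategy,
         cutoff = if (strategy == "firstline_nipt") NA_real_ else cutoff,
         uptake_scenario = uptake_scenario,
         include_pregnancy_outcome_costs = include_pregnancy_outcome_costs,
         separate_nipt_blood_draw = separate_nipt_blood_draw),
    class = "strategy_spec"
  )
}

#' Combined-test performance at a risk cut-off
#'
#' @param params A `nipt_params` bundle.
#' @param cutoff Risk cut-off denominator.
#' @return List with `detection_rate` and `false_positive_rate`.
#' @export
combined_performance <- function(params, cutoff) {
  perf <- params$screening$combined[[as.character(cutoff)]]
  if (is.null(perf)) {
    abort(paste0("No combined-test performance for cut-off 1 in ", cutoff, "."))
  }
  perf
}

#' Nuchal-translucency measurement failure rate at a gestational week
#'
#' Linear interpolation between the rates at the first and last week of the
#' combined-test window, clamped outside it.
#'
#' @param params A `nipt_params` bundle.
#' @param week Gestational week.
#' @return Failure probability.
#' @export
nt_failure_rate <- function(params, week) {
  nf <- params$screening$nt_failure
  approx(x = c(nf$first_week, nf$last_week),
         y = c(nf$first_rate, nf$last_rate),
         xout = week, rule = 2)$y
}

#' @export
print.nipt_params <- function(x, ...) {
  cat("<nipt_params>\n")
  cat("  cohort size:       ", x$cohort_size, "\n")
  cat("  screening uptake:  ", x$uptakes$screening,
      " (late arrivals ", x$uptakes$late_arrival, ")\n", sep = "")
  cat("  NIPT DR/FPR:       ", x$nipt$detection_rate, "/",
      x$nipt$false_positive_rate, "\n", sep = "")
  cat("  NIPT unit cost:    GBP", x$costs$nipt_test, "\n")
  cat("  combined cut-offs: ",
      paste(names(x$screening$combined), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a parameter bundle
#'
#' @param x A `nipt_params` bundle.
#' @param ... Unused.
#' @return A tibble with one row per scalar parameter (`key`, `value`), keys
#'   in dotted-path form.
#' @method tidy nipt_params
#' @export
tidy.nipt_params <- function(x, ...) {
  flat <- flatten_params(unclass(x), path = character())
  tibble::tibble(key = names(flat), value = unname(unlist(flat)))
}

# --- internals --------------------------------------------------------------

flatten_params <- function(x, path) {
  if (!is.list(x)) {
    return(setNames(list(x), paste(path, collapse = ".")))
  }
  out <- list()
  for (nm in names(x)) {
    out <- c(out, flatten_params(x[[nm]], c(path, nm)))
  }
  out
}

# Strict recursive merge: overrides must only touch keys that exist in the
# defaults, and must not replace a sub-list with a scalar (or vice versa).
merge_strict <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  if (!is.list(overrides) || is.null(names(overrides)) ||
      any(names(overrides) == "")) {
    abort(paste0("Configuration section '", paste(path, collapse = "."),
                 "' must be a named mapping."))
  }
  for (nm in names(overrides)) {
    here <- c(path, nm)
    if (!nm %in% names(defaults)) {
      abort(paste0("Unknown configuration key: '",
                   paste(here, collapse = "."), "'."))
    }
    if (is.list(defaults[[nm]])) {
      if (!is.list(overrides[[nm]])) {
        abort(paste0("Configuration key '", paste(here, collapse = "."),
                     "' must be a mapping."))
      }
      defaults[[nm]] <- merge_strict(defaults[[nm]], overrides[[nm]], here)
    } else {
      value <- overrides[[nm]]
      if (is.list(value) || length(value) != 1) {
        abort(paste0("Configuration key '", paste(here, collapse = "."),
                     "' must be a single value."))
      }
      defaults[[nm]] <- value
    }
  }
  defaults
}

check_prob <- function(value, key) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    abort(paste0("Parameter '", key, "' must be a probability in [0, 1]; got ",
                 format(value), "."))
  }
  invisible(value)
}

check_cost <- function(value, key) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) || value < 0) {
    abort(paste0("Parameter '", key, "' must be a non-negative cost; got ",
                 format(value), "."))
  }
  invisible(value)
}

validate_parameters <- function(params) {
  if (!is.numeric(params$cohort_size) || params$cohort_size < 0) {
    abort("Parameter 'cohort_size' must be a non-negative count.")
  }
  cutoffs <- names(params$screening$combined)
  for (co in cutoffs) {
    perf <- params$screening$combined[[co]]
    check_prob(perf$detection_rate,
               paste0("screening.combined.", co, ".detection_rate"))
    check_prob(perf$false_positive_rate,
               paste0("screening.combined.", co, ".false_positive_rate"))
  }
  drs <- vapply(params$screening$combined, `[[`, 0, "detection_rate")
  fprs <- vapply(params$screening$combined, `[[`, 0, "false_positive_rate")
  ord <- order(as.numeric(cutoffs))
  if (any(diff(drs[ord]) <= 0) || any(diff(fprs[ord]) <= 0)) {
    abort(paste0("Combined-test detection and false-positive rates must both ",
                 "increase strictly with the risk cut-off denominator."))
  }
  check_prob(params$screening$quadruple$detection_rate,
             "screening.quadruple.detection_rate")
  check_prob(params$screening$quadruple$false_positive_rate,
             "screening.quadruple.false_positive_rate")
  for (nm in c("first_rate", "last_rate")) {
    check_prob(params$screening$nt_failure[[nm]],
               paste0("screening.nt_failure.", nm))
  }
  for (test in c("cvs", "amniocentesis")) {
    for (nm in c("detection_rate", "sample_failure_rate",
                 "procedure_miscarriage_rate")) {
      check_prob(params$invasive[[test]][[nm]],
                 paste0("invasive.", test, ".", nm))
    }
  }
  for (nm in c("detection_rate", "false_positive_rate", "sample_failure_rate",
               "procedure_miscarriage_rate")) {
    check_prob(params$nipt[[nm]], paste0("nipt.", nm))
  }
  for (grp in names(params$loss_rates)) {
    for (nm in names(params$loss_rates[[grp]])) {
      key <- paste0("loss_rates.", grp, ".", nm)
      check_prob(params$loss_rates[[grp]][[nm]], key)
      if (params$loss_rates[[grp]][[nm]] >= 1) {
        abort(paste0("Parameter '", key, "' must be a weekly hazard < 1."))
      }
    }
  }
  for (nm in names(params$uptakes)) {
    check_prob(params$uptakes[[nm]], paste0("uptakes.", nm))
  }
  check_prob(params$birth_mode$vaginal, "birth_mode.vaginal")
  check_prob(params$birth_mode$caesarean, "birth_mode.caesarean")
  if (abs(params$birth_mode$vaginal + params$birth_mode$caesarean - 1) > 1e-9) {
    abort("Parameters 'birth_mode.vaginal' and 'birth_mode.caesarean' must sum to 1.")
  }
  for (nm in names(params$costs)) {
    check_cost(params$costs[[nm]], paste0("costs.", nm))
  }
  for (nm in names(params$timing)) {
    wk <- params$timing[[nm]]
    if (!is.numeric(wk) || wk < 10 || wk > 40) {
      abort(paste0("Parameter 'timing.", nm,
                   "' must be a gestational week in [10, 40]."))
    }
  }
  check_prob(params$prevalence$week10_cohort_prevalence,
             "prevalence.week10_cohort_prevalence")
  params
}
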