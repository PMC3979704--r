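#' Ledger field names of a pathway run
#'
#' Expected event counts tracked by the deterministic engine (and realised
#' counts tabulated by the microsimulator). Counts are split by affected
#' status where the split matters for costing or conservation.
#'
#' @return Character vector of field names.
#' @export
pathway_event_fields <- function() {
  c("n_screened_t1", "n_screened_t2", "n_repeat_nt",
    "n_screen_positive_affected", "n_screen_positive_unaffected",
    "n_nipt_takers", "n_nipt_tests",
    "n_nipt_positive_affected", "n_nipt_positive_unaffected",
    "n_cvs", "n_amniocentesis",
    "n_invasive_affected", "n_invasive_unaffected", "n_invasive_repeats",
    "n_procedure_miscarriages_affected", "n_procedure_miscarriages_unaffected",
    "n_ds_detected", "n_top_t1", "n_top_t2",
    "n_spontaneous_loss_affected", "n_spontaneous_loss_unaffected",
    "n_vaginal_births_affected", "n_vaginal_births_unaffected",
    "n_caesarean_births_affected", "n_caesarean_births_unaffected")
}

empty_events <- function() {
  setNames(numeric(length(pathway_event_fields())), pathway_event_fields())
}

#' Apply a screening test to a cohort slice
#'
#' Uptake selects the takers; DS-affected takers screen positive at the
#' detection rate and unaffected takers at the false-positive rate. The four
#' outputs (positives, negatives, decliners by status) partition the input
#' slice exactly.
#'
#' @param slice A [cohort_slice()] at the screening week.
#' @param perf Test performance: list with `detection_rate` and
#'   `false_positive_rate`.
#' @param uptake Screening uptake probability.
#' @return List with `takers` (slice), `positives`, `negatives` (named
#'   vectors by status) and `decliners` (slice).
#' @export
apply_screening <- function(slice, perf, uptake) {
  t_a <- slice$affected * uptake
  t_u <- slice$unaffected * uptake
  p_a <- t_a * perf$detection_rate
  p_u <- t_u * perf$false_positive_rate
  list(
    takers = cohort_slice(t_a, t_u, slice$week),
    positives = c(affected = p_a, unaffected = p_u),
    negatives = c(affected = t_a - p_a, unaffected = t_u - p_u),
    decliners = cohort_slice(slice$affected - t_a, slice$unaffected - t_u,
                             slice$week)
  )
}

#' Apply NIPT to screen-positive (or first-line) candidates
#'
#' Each taker undergoes one NIPT; the sample fails with the failure rate and
#' is then repeated exactly once (always yielding a result), so the expected
#' number of tests is takers times one plus the failure rate. NIPT carries no
#' procedural loss.
#'
#' @param candidates Named vector (`affected`, `unaffected`) of candidate
#'   counts.
#' @param nipt NIPT performance list (`detection_rate`,
#'   `false_positive_rate`, `sample_failure_rate`).
#' @param uptake Either a single probability or a named vector with
#'   `affected` and `unaffected` uptakes.
#' @return List with `takers`, `positives`, `negatives`, `decliners` (named
#'   vectors by status) and `nipt_tests` (scalar, including repeats).
#' @export
apply_nipt <- function(candidates, nipt, uptake) {
  if (length(uptake) == 1) {
    uptake <- c(affected = unname(uptake), unaffected = unname(uptake))
  }
  t_a <- candidates[["affected"]] * uptake[["affected"]]
  t_u <- candidates[["unaffected"]] * uptake[["unaffected"]]
  p_a <- t_a * nipt$detection_rate
  p_u <- t_u * nipt$false_positive_rate
  list(
    takers = c(affected = t_a, unaffected = t_u),
    nipt_tests = (t_a + t_u) * (1 + nipt$sample_failure_rate),
    positives = c(affected = p_a, unaffected = p_u),
    negatives = c(affected = t_a - p_a, unaffected = t_u - p_u),
    decliners = c(affected = candidates[["affected"]] - t_a,
                  unaffected = candidates[["unaffected"]] - t_u)
  )
}

#' Apply an invasive diagnostic test
#'
#' Takers undergo CVS or amniocentesis; sample failures trigger one repeat
#' procedure (extra test, no extra miscarriage risk); each procedure carries
#' the procedural miscarriage risk, drawn proportionally from both statuses.
#' A DS pregnancy lost to the procedure is not counted as detected, so
#' `confirmed_ds = affected takers x DR x (1 - miscarriage rate)`. Decliners
#' are never detected.
#'
#' @param candidates Named vector (`affected`, `unaffected`).
#' @param test Invasive test performance list (`detection_rate`,
#'   `sample_failure_rate`, `procedure_miscarriage_rate`).
#' @param uptake Named vector with `affected` and `unaffected` uptakes (or a
#'   single probability).
#' @return List with `takers` (by status), `n_invasive`, `n_repeats`,
#'   `n_miscarriages` (by status), `confirmed_ds`, `undetected_affected`
#'   (takers missed by an imperfect test), `cleared_unaffected` and
#'   `decliners` (by status).
#' @export
apply_invasive <- function(candidates, test, uptake) {
  if (length(uptake) == 1) {
    uptake <- c(affected = unname(uptake), unaffected = unname(uptake))
  }
  t_a <- candidates[["affected"]] * uptake[["affected"]]
  t_u <- candidates[["unaffected"]] * uptake[["unaffected"]]
  n_inv <- t_a + t_u
  m_a <- t_a * test$procedure_miscarriage_rate
  m_u <- t_u * test$procedure_miscarriage_rate
  confirmed <- (t_a - m_a) * test$detection_rate
  list(
    takers = c(affected = t_a, unaffected = t_u),
    n_invasive = n_inv,
    n_repeats = n_inv * test$sample_failure_rate,
    n_miscarriages = c(affected = m_a, unaffected = m_u),
    confirmed_ds = confirmed,
    undetected_affected = (t_a - m_a) - confirmed,
    cleared_unaffected = t_u - m_u,
    decliners = c(affected = candidates[["affected"]] - t_a,
                  unaffected = candidates[["unaffected"]] - t_u)
  )
}

#' Termination uptake and delivery outcomes
#'
#' Confirmed DS diagnoses accept termination of pregnancy at the TOP uptake,
#' booked to the trimester of the diagnosis week; everyone else propagates to
#' week 40 under the fetal-loss hazards and delivers vaginally or by
#' caesarean section at the population mode split.
#'
#' @param confirmed_ds Expected confirmed DS diagnoses at `diagnosis_week`.
#' @param undetected A [cohort_slice()] of pregnancies continuing without a
#'   diagnosis (any status), at its own week.
#' @param params A `nipt_params` bundle.
#' @param diagnosis_week Gestational week of the confirmed diagnoses.
#' @return List with `n_top_t1`, `n_top_t2`, `births` (named vector
#'   `vaginal_affected`, `caesarean_affected`, `vaginal_unaffected`,
#'   `caesarean_unaffected`) and `late_losses` (by status).
#' @export
apply_top_and_births <- function(confirmed_ds, undetected, params,
                                 diagnosis_week) {
  tops <- confirmed_ds * params$uptakes$top
  t1 <- diagnosis_week <= params$timing$first_trimester_max_week
  continuing_aff <- confirmed_ds - tops
  r1 <- advance(cohort_slice(continuing_aff, 0, diagnosis_week), 40, params)
  r2 <- advance(undetected, 40, params)
  bm <- params$birth_mode
  aff_at_term <- r1$slice$affected + r2$slice$affected
  un_at_term <- r2$slice$unaffected
  list(
    n_top_t1 = if (t1) tops else 0,
    n_top_t2 = if (t1) 0 else tops,
    births = c(vaginal_affected = aff_at_term * bm$vaginal,
               caesarean_affected = aff_at_term * bm$caesarean,
               vaginal_unaffected = un_at_term * bm$vaginal,
               caesarean_unaffected = un_at_term * bm$caesarean),
    late_losses = c(affected = r1$losses[["affected"]] + r2$losses[["affected"]],
                    unaffected = r2$losses[["unaffected"]])
  )
}

# Deterministic expected-value engine shared by the three strategies.
run_strategy_engine <- function(params, spec, cohort) {
  up <- params$uptakes
  tm <- params$timing
  ledger <- empty_events()
  terminal_pool <- list()

  add <- function(field, x) ledger[[field]] <<- ledger[[field]] + x
  spont <- function(losses) {
    add("n_spontaneous_loss_affected", losses[["affected"]])
    add("n_spontaneous_loss_unaffected", losses[["unaffected"]])
  }
  to_term <- function(slice) {
    terminal_pool[[length(terminal_pool) + 1]] <<- slice
  }
  move <- function(slice, wk) {
    r <- advance(slice, wk, params)
    spont(r$losses)
    r$slice
  }

  do_invasive <- function(candidates, wk, test_name) {
    inv <- apply_invasive(candidates, params$invasive[[test_name]],
                          c(affected = up$invasive_affected,
                            unaffected = up$invasive_unaffected))
    to_term(cohort_slice(inv$decliners[["affected"]],
                         inv$decliners[["unaffected"]], wk))
    add(if (test_name == "cvs") "n_cvs" else "n_amniocentesis", inv$n_invasive)
    add("n_invasive_affected", inv$takers[["affected"]])
    add("n_invasive_unaffected", inv$takers[["unaffected"]])
    add("n_invasive_repeats", inv$n_repeats)
    add("n_procedure_miscarriages_affected", inv$n_miscarriages[["affected"]])
    add("n_procedure_miscarriages_unaffected", inv$n_miscarriages[["unaffected"]])
    add("n_ds_detected", inv$confirmed_ds)
    tops <- inv$confirmed_ds * up$top
    if (wk <= tm$first_trimester_max_week) {
      add("n_top_t1", tops)
    } else {
      add("n_top_t2", tops)
    }
    to_term(cohort_slice(inv$confirmed_ds - tops + inv$undetected_affected,
                         inv$cleared_unaffected, wk))
  }

  do_nipt <- function(candidates, wk, uptake, invasive_wk, invasive_test) {
    res <- apply_nipt(c(affected = candidates$affected,
                        unaffected = candidates$unaffected),
                      params$nipt, uptake)
    add("n_nipt_takers", sum(res$takers))
    add("n_nipt_tests", res$nipt_tests)
    add("n_nipt_positive_affected", res$positives[["affected"]])
    add("n_nipt_positive_unaffected", res$positives[["unaffected"]])
    to_term(cohort_slice(res$decliners[["affected"]],
                         res$decliners[["unaffected"]], wk))
    to_term(cohort_slice(res$negatives[["affected"]],
                         res$negatives[["unaffected"]], wk))
    pos <- move(cohort_slice(res$positives[["affected"]],
                             res$positives[["unaffected"]], wk), invasive_wk)
    do_invasive(pos, invasive_wk, invasive_test)
  }

  do_screen_arm <- function(pool, screen_wk, perf, is_t1) {
    s <- move(pool, screen_wk)
    scr <- apply_screening(s, perf, up$screening)
    n_takers <- scr$takers$affected + scr$takers$unaffected
    add(if (is_t1) "n_screened_t1" else "n_screened_t2", n_takers)
    if (is_t1) {
      add("n_repeat_nt", n_takers * nt_failure_rate(params, screen_wk))
    }
    add("n_screen_positive_affected", scr$positives[["affected"]])
    add("n_screen_positive_unaffected", scr$positives[["unaffected"]])
    to_term(scr$decliners)
    to_term(cohort_slice(scr$negatives[["affected"]],
                         scr$negatives[["unaffected"]], screen_wk))
    cohort_slice(scr$positives[["affected"]], scr$positives[["unaffected"]],
                 screen_wk)
  }

  if (spec$strategy %in% c("current", "contingent_nipt")) {
    late <- up$late_arrival
    t1_pool <- cohort_slice(cohort$affected * (1 - late),
                            cohort$unaffected * (1 - late), cohort$week)
    t2_pool <- cohort_slice(cohort$affected * late,
                            cohort$unaffected * late, cohort$week)
    pos1 <- do_screen_arm(t1_pool, tm$combined_screen,
                          combined_performance(params, spec$cutoff), TRUE)
    pos2 <- do_screen_arm(t2_pool, tm$quadruple_screen,
                          params$screening$quadruple, FALSE)
    if (spec$strategy == "current") {
      do_invasive(move(pos1, tm$cvs), tm$cvs, "cvs")
      do_invasive(move(pos2, tm$amniocentesis), tm$amniocentesis,
                  "amniocentesis")
    } else {
      nipt_uptake <- c(affected = up$nipt_affected,
                       unaffected = up$nipt_unaffected)
      do_nipt(move(pos1, tm$contingent_nipt_t1), tm$contingent_nipt_t1,
              nipt_uptake, tm$contingent_invasive_t1, "cvs")
      do_nipt(move(pos2, tm$contingent_nipt_t2), tm$contingent_nipt_t2,
              nipt_uptake, tm$contingent_invasive_t2, "amniocentesis")
    }
  } else {
    pool <- move(cohort, tm$firstline_nipt)
    do_nipt(pool, tm$firstline_nipt, up$nipt_firstline,
            tm$firstline_invasive, "cvs")
  }

  bm <- params$birth_mode
  for (slice in terminal_pool) {
    r <- advance(slice, 40, params)
    spont(r$losses)
    add("n_vaginal_births_affected", r$slice$affected * bm$vaginal)
    add("n_caesarean_births_affected", r$slice$affected * bm$caesarean)
    add("n_vaginal_births_unaffected", r$slice$unaffected * bm$vaginal)
    add("n_caesarean_births_unaffected", r$slice$unaffected * bm$caesarean)
  }

  structure(
    list(events = ledger, spec = spec, params = params, cohort = cohort),
    class = "nipt_run"
  )
}

#' Run the current screening programme
#'
#' Combined test (first trimester, invasive follow-up by CVS) for 85% of the
#' cohort and quadruple test (second trimester, amniocentesis) for the 15%
#' booking late; screen-positives are offered invasive testing directly.
#'
#' @param params A `nipt_params` bundle.
#' @param spec A [strategy_spec()]; built from `cutoff` if `NULL`.
#' @param cutoff Screening risk cut-off denominator used when `spec` is NULL.
#' @param cohort Optional [cohort_slice()] at week 10; defaults to
#'   [initial_cohort()] under the packaged age/prevalence tables.
#' @return A `nipt_run` object: the event ledger plus run metadata. Use
#'   [summarize_outcomes()], [glance()][generics::glance] or
#'   [tidy()][generics::tidy] on it.
#' @examples
#' run <- run_current_screening(default_parameters())
#' glance(run)
#' @export
run_current_screening <- function(params, spec = NULL, cutoff = 150,
                                  cohort = NULL) {
  spec <- spec %||% strategy_spec("current", cutoff = cutoff)
  stopifnot(spec$strategy == "current")
  cohort <- cohort %||% initial_cohort(params)
  run_strategy_engine(params, spec, cohort)
}

#' Run NIPT as contingent testing
#'
#' Identical screening stage to [run_current_screening()]; screen-positive
#' women are offered NIPT, and only NIPT-positive women are offered an
#' invasive test. Detection requires invasive confirmation, so DS cases whose
#' carriers decline the invasive test are not detected.
#'
#' @inheritParams run_current_screening
#' @return A `nipt_run` object.
#' @export
run_contingent_nipt <- function(params, spec = NULL, cutoff = 150,
                                cohort = NULL) {
  spec <- spec %||% strategy_spec("contingent_nipt", cutoff = cutoff)
  stopifnot(spec$strategy == "contingent_nipt")
  cohort <- cohort %||% initial_cohort(params)
  run_strategy_engine(params, spec, cohort)
}

#' Run NIPT as first-line testing
#'
#' No conventional screening; the whole cohort is offered NIPT (base uptake
#' 69%), and NIPT-positive women are offered invasive confirmation.
#'
#' @inheritParams run_current_screening
#' @return A `nipt_run` object with zero screening events.
#' @export
run_firstline_nipt <- function(params, spec = NULL, cohort = NULL) {
  spec <- spec %||% strategy_spec("firstline_nipt")
  stopifnot(spec$strategy == "firstline_nipt")
  cohort <- cohort %||% initial_cohort(params)
  run_strategy_engine(params, spec, cohort)
}

#' Run a strategy given its specification
#'
#' Dispatches to the three strategy runners, applying any uptake-scenario
#' overrides named in `spec$uptake_scenario` first.
#'
#' @inheritParams run_current_screening
#' @param spec A [strategy_spec()].
#' @param apply_scenario Apply [scenario_presets()] overrides matching
#'   `spec$uptake_scenario` (default TRUE; "base" applies none).
#' @return A `nipt_run` object.
#' @export
run_strategy <- function(params, spec, cohort = NULL, apply_scenario = TRUE) {
  if (apply_scenario && !spec$uptake_scenario %in% c("base", "base_contingent")) {
    params <- load_parameters(
      modifyList(unclass(params),
                 scenario_presets(spec$uptake_scenario)$overrides)
    )
  }
  cohort <- cohort %||% initial_cohort(params)
  switch(spec$strategy,
    current = run_current_screening(params, spec, cohort = cohort),
    contingent_nipt = run_contingent_nipt(params, spec, cohort = cohort),
    firstline_nipt = run_firstline_nipt(params, spec, cohort = cohort)
  )
}

#' Summarise a run into the headline outcome columns
#'
#' The six outcome measures reported per strategy: women undergoing
#' screening, undergoing NIPT, with a positive NIPT result, having an
#' invasive diagnostic test, procedure-related miscarriages, and DS cases
#' detected.
#'
#' @param x A `nipt_run` object or a named event vector.
#' @return A one-row tibble.
#' @export
summarize_outcomes <- function(x) {
  events <- if (inherits(x, "nipt_run")) x$events else x
  spec <- if (inherits(x, "nipt_run")) x$spec else NULL
  tibble::tibble(
    strategy = if (is.null(spec)) NA_character_ else spec$strategy,
    cutoff = if (is.null(spec)) NA_real_ else spec$cutoff,
    n_screened = events[["n_screened_t1"]] + events[["n_screened_t2"]],
    n_nipt = events[["n_nipt_takers"]],
    n_nipt_positive = events[["n_nipt_positive_affected"]] +
      events[["n_nipt_positive_unaffected"]],
    n_invasive = events[["n_invasive_affected"]] +
      events[["n_invasive_unaffected"]],
    n_procedure_miscarriages = events[["n_procedure_miscarriages_affected"]] +
      events[["n_procedure_miscarriages_unaffected"]],
    n_ds_detected = events[["n_ds_detected"]]
  )
}

#' Check cohort conservation of a run
#'
#' Every pregnancy in the initial cohort must end in exactly one terminal
#' state: spontaneous loss, procedure-related miscarriage, termination, or
#' live birth.
#'
#' @param run A `nipt_run` object.
#' @return Named vector with the absolute discrepancy per status, invisibly;
#'   the run conserves the cohort when both are ~0.
#' @export
conservation_error <- function(run) {
  e <- run$events
  aff_out <- e[["n_spontaneous_loss_affected"]] +
    e[["n_procedure_miscarriages_affected"]] +
    e[["n_top_t1"]] + e[["n_top_t2"]] +
    e[["n_vaginal_births_affected"]] + e[["n_caesarean_births_affected"]]
  un_out <- e[["n_spontaneous_loss_unaffected"]] +
    e[["n_procedure_miscarriages_unaffected"]] +
    e[["n_vaginal_births_unaffected"]] + e[["n_caesarean_births_unaffected"]]
  c(affected = abs(aff_out - run$cohort$affected),
    unaffected = abs(un_out - run$cohort$unaffected))
}

#' @export
print.nipt_run <- function(x, ...) {
  cat("<nipt_run>", x$spec$strategy,
      if (!is.na(x$spec$cutoff)) paste0("(cut-off 1 in ", x$spec$cutoff, ")"),
      "\n")
  print(summarize_outcomes(x))
  invisible(x)
}

#' Tidy a pathway run into a long event table
#'
#' @param x A `nipt_run` object.
#' @param ... Unused.
#' @return A tibble with columns `event` and `count`.
#' @method tidy nipt_run
#' @export
tidy.nipt_run <- function(x, ...) {
  tibble::tibble(event = names(x$events), count = unname(x$events))
}

#' One-row summary of a pathway run
#'
#' @param x A `nipt_run` object.
#' @param ... Unused.
#' @return The [summarize_outcomes()] tibble.
#' @method glance nipt_run
#' @export
glance.nipt_run <- function(x, ...) {
  summarize_outcomes(x)
}

#' Plot the outcome profile of one or more runs
#'
#' @param object A `nipt_run` object.
#' @param ... Further `nipt_run` objects to compare.
#' @return A ggplot object: outcome measures per strategy.
#' @method autoplot nipt_run
#' @export
autoplot.nipt_run <- function(object, ...) {
  runs <- c(list(object), Filter(function(x) inherits(x, "nipt_run"),
                                 list(...)))
  df <- purrr::map_dfr(runs, summarize_outcomes)
  df$label <- paste0(df$strategy,
                     ifelse(is.na(df$cutoff), "", paste0(" 1:", df$cutoff)))
  long <- tidyr::pivot_longer(
    df, c("n_screened", "n_nipt", "n_nipt_positive", "n_invasive",
          "n_procedure_miscarriages", "n_ds_detected"),
    names_to = "measure", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Expected count per cohort") +
    ggplot2::theme_minimal()
}
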