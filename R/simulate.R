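# Draw-slot layout: each simulated woman consumes one fixed row of uniform
# variates, so trajectories are reproducible and growing n never reshuffles
# earlier women (woman i uses draws (i-1)*K+1 .. i*K of the seeded stream).
SIM_SLOTS <- c(age = 1, affected = 2, late_booking = 3, screen_uptake = 4,
               screen_result = 5, nt_repeat = 6, nipt_uptake = 7,
               nipt_failure = 8, nipt_result = 9, invasive_uptake = 10,
               invasive_failure = 11, procedure_miscarriage = 12,
               top_uptake = 13, loss_time = 14, birth_mode = 15,
               invasive_result = 16)

#' Simulate individual pregnancy trajectories
#'
#' Individual-level counterpart of the deterministic expectation engine:
#' each woman's pathway is drawn by independent Bernoulli events at exactly
#' the rates in `params`, under the same age distribution and prevalence
#' model, so tabulated event counts converge to the deterministic ledger.
#' Spontaneous loss uses a single uniform per woman inverted through the
#' cumulative weekly survival curve of her affected status, which reproduces
#' the weekly-hazard chain exactly.
#'
#' @param params A `nipt_params` bundle.
#' @param spec A [strategy_spec()].
#' @param n Number of women to simulate.
#' @param seed Integer seed; the same `(params, spec, n, seed)` always
#'   yields identical trajectories.
#' @param ages Age-distribution tibble (see [default_age_distribution()]).
#' @param prev Optional `nipt_prevalence` object.
#' @return A tibble with one row per woman: demographics, per-stage realised
#'   events, and the terminal state (`birth`, `spontaneous_loss`,
#'   `procedural_miscarriage` or `top`).
#' @seealso [tabulate_events()], [compare_to_expectation()]
#' @export
simulate_women <- function(params, spec, n, seed,
                           ages = default_age_distribution(), prev = NULL) {
  if (n <= 0) abort("Require n > 0 women.")
  if (is.null(prev)) prev <- prevalence_model(params, ages)
  set.seed(as.integer(seed))
  k <- length(SIM_SLOTS)
  u <- matrix(runif(n * k), nrow = n, ncol = k, byrow = TRUE)
  draw <- function(slot) u[, SIM_SLOTS[[slot]]]

  up <- params$uptakes
  tm <- params$timing

  age_idx <- findInterval(draw("age"), c(0, cumsum(ages$proportion)),
                          rightmost.closed = TRUE)
  age_idx <- pmin(pmax(age_idx, 1), nrow(ages))
  age <- ages$age[age_idx]
  q10 <- prev$table$week10_risk[match(age, prev$table$age)]
  affected <- draw("affected") < q10

  # cumulative survival from week 10 to the start of each week, per status
  surv_curve <- function(status) {
    haz <- loss_hazard(params, status, 10:39)
    c(1, cumprod(1 - haz)) # index w - 9 gives survival to week w
  }
  s_aff <- surv_curve("affected")
  s_un <- surv_curve("unaffected")
  alive_at <- function(week) {
    s <- ifelse(affected, s_aff[week - 9], s_un[week - 9])
    draw("loss_time") < s
  }

  late <- draw("late_booking") < up$late_arrival
  screened <- rep(FALSE, n)
  nt_repeat <- rep(FALSE, n)
  screen_positive <- rep(FALSE, n)
  nipt_taken <- rep(FALSE, n)
  nipt_test_repeat <- rep(FALSE, n)
  nipt_positive <- rep(FALSE, n)
  inv_candidate <- rep(FALSE, n)
  inv_week <- rep(NA_real_, n)
  inv_type <- rep(NA_character_, n)

  if (spec$strategy %in% c("current", "contingent_nipt")) {
    screen_week <- ifelse(late, tm$quadruple_screen, tm$combined_screen)
    screened <- (draw("screen_uptake") < up$screening) & alive_at(screen_week)
    comb <- combined_performance(params, spec$cutoff)
    quad <- params$screening$quadruple
    pos_rate <- ifelse(late,
                       ifelse(affected, quad$detection_rate,
                              quad$false_positive_rate),
                       ifelse(affected, comb$detection_rate,
                              comb$false_positive_rate))
    screen_positive <- screened & (draw("screen_result") < pos_rate)
    nt_repeat <- screened & !late &
      (draw("nt_repeat") < nt_failure_rate(params, tm$combined_screen))
    if (spec$strategy == "current") {
      inv_week <- ifelse(late, tm$amniocentesis, tm$cvs)
      inv_type <- ifelse(late, "amniocentesis", "cvs")
      inv_candidate <- screen_positive & alive_at(inv_week)
    } else {
      nipt_week <- ifelse(late, tm$contingent_nipt_t2, tm$contingent_nipt_t1)
      nipt_uptake <- ifelse(affected, up$nipt_affected, up$nipt_unaffected)
      nipt_taken <- screen_positive & alive_at(nipt_week) &
        (draw("nipt_uptake") < nipt_uptake)
      nipt_test_repeat <- nipt_taken &
        (draw("nipt_failure") < params$nipt$sample_failure_rate)
      nipt_result_rate <- ifelse(affected, params$nipt$detection_rate,
                                 params$nipt$false_positive_rate)
      nipt_positive <- nipt_taken & (draw("nipt_result") < nipt_result_rate)
      inv_week <- ifelse(late, tm$contingent_invasive_t2,
                         tm$contingent_invasive_t1)
      inv_type <- ifelse(late, "amniocentesis", "cvs")
      inv_candidate <- nipt_positive & alive_at(inv_week)
    }
  } else {
    nipt_week <- rep(tm$firstline_nipt, n)
    nipt_taken <- alive_at(nipt_week) &
      (draw("nipt_uptake") < up$nipt_firstline)
    nipt_test_repeat <- nipt_taken &
      (draw("nipt_failure") < params$nipt$sample_failure_rate)
    nipt_result_rate <- ifelse(affected, params$nipt$detection_rate,
                               params$nipt$false_positive_rate)
    nipt_positive <- nipt_taken & (draw("nipt_result") < nipt_result_rate)
    inv_week <- rep(tm$firstline_invasive, n)
    inv_type <- rep("cvs", n)
    inv_candidate <- nipt_positive & alive_at(inv_week)
  }

  inv_uptake <- ifelse(affected, up$invasive_affected, up$invasive_unaffected)
  invasive_taken <- inv_candidate & (draw("invasive_uptake") < inv_uptake)
  fail_rate <- ifelse(inv_type == "cvs",
                      params$invasive$cvs$sample_failure_rate,
                      params$invasive$amniocentesis$sample_failure_rate)
  misc_rate <- ifelse(inv_type == "cvs",
                      params$invasive$cvs$procedure_miscarriage_rate,
                      params$invasive$amniocentesis$procedure_miscarriage_rate)
  det_rate <- ifelse(inv_type == "cvs",
                     params$invasive$cvs$detection_rate,
                     params$invasive$amniocentesis$detection_rate)
  invasive_repeat <- invasive_taken & (draw("invasive_failure") < fail_rate)
  procedure_miscarriage <- invasive_taken &
    (draw("procedure_miscarriage") < misc_rate)
  ds_detected <- invasive_taken & affected & !procedure_miscarriage &
    (draw("invasive_result") < det_rate)
  top <- ds_detected & (draw("top_uptake") < up$top)
  top_trimester <- ifelse(top,
                          ifelse(inv_week <= tm$first_trimester_max_week,
                                 1L, 2L),
                          NA_integer_)

  survives_to_term <- alive_at(40)
  terminal <- dplyr::case_when(
    procedure_miscarriage ~ "procedural_miscarriage",
    top ~ "top",
    survives_to_term ~ "birth",
    TRUE ~ "spontaneous_loss"
  )
  caesarean <- terminal == "birth" &
    (draw("birth_mode") < params$birth_mode$caesarean)

  tibble::tibble(
    maternal_age = age,
    affected = affected,
    booking = ifelse(late, "second", "first"),
    screened = screened,
    nt_repeat = nt_repeat,
    screen_positive = screen_positive,
    nipt_taken = nipt_taken,
    nipt_test_repeat = nipt_test_repeat,
    nipt_positive = nipt_positive,
    invasive_taken = invasive_taken,
    invasive_type = ifelse(invasive_taken, inv_type, NA_character_),
    invasive_repeat = invasive_repeat,
    procedure_miscarriage = procedure_miscarriage,
    ds_detected = ds_detected,
    top = top,
    top_trimester = top_trimester,
    terminal = terminal,
    caesarean = caesarean
  )
}

#' Tabulate simulated trajectories into a pathway event ledger
#'
#' Realised counts in the same ledger shape as the deterministic engine
#' (see [pathway_event_fields()]), enabling direct comparison.
#'
#' @param women Tibble from [simulate_women()].
#' @return Named numeric vector of event counts.
#' @export
tabulate_events <- function(women) {
  e <- empty_events()
  if (nrow(women) == 0) return(e)
  w <- women
  t1 <- w$booking == "first"
  e[["n_screened_t1"]] <- sum(w$screened & t1)
  e[["n_screened_t2"]] <- sum(w$screened & !t1)
  e[["n_repeat_nt"]] <- sum(w$nt_repeat)
  e[["n_screen_positive_affected"]] <- sum(w$screen_positive & w$affected)
  e[["n_screen_positive_unaffected"]] <- sum(w$screen_positive & !w$affected)
  e[["n_nipt_takers"]] <- sum(w$nipt_taken)
  e[["n_nipt_tests"]] <- sum(w$nipt_taken) + sum(w$nipt_test_repeat)
  e[["n_nipt_positive_affected"]] <- sum(w$nipt_positive & w$affected)
  e[["n_nipt_positive_unaffected"]] <- sum(w$nipt_positive & !w$affected)
  e[["n_cvs"]] <- sum(w$invasive_taken & w$invasive_type == "cvs", na.rm = TRUE)
  e[["n_amniocentesis"]] <- sum(w$invasive_taken &
                                  w$invasive_type == "amniocentesis",
                                na.rm = TRUE)
  e[["n_invasive_affected"]] <- sum(w$invasive_taken & w$affected)
  e[["n_invasive_unaffected"]] <- sum(w$invasive_taken & !w$affected)
  e[["n_invasive_repeats"]] <- sum(w$invasive_repeat)
  e[["n_procedure_miscarriages_affected"]] <-
    sum(w$procedure_miscarriage & w$affected)
  e[["n_procedure_miscarriages_unaffected"]] <-
    sum(w$procedure_miscarriage & !w$affected)
  e[["n_ds_detected"]] <- sum(w$ds_detected)
  e[["n_top_t1"]] <- sum(w$top & w$top_trimester == 1L, na.rm = TRUE)
  e[["n_top_t2"]] <- sum(w$top & w$top_trimester == 2L, na.rm = TRUE)
  e[["n_spontaneous_loss_affected"]] <-
    sum(w$terminal == "spontaneous_loss" & w$affected)
  e[["n_spontaneous_loss_unaffected"]] <-
    sum(w$terminal == "spontaneous_loss" & !w$affected)
  e[["n_vaginal_births_affected"]] <-
    sum(w$terminal == "birth" & w$affected & !w$caesarean)
  e[["n_vaginal_births_unaffected"]] <-
    sum(w$terminal == "birth" & !w$affected & !w$caesarean)
  e[["n_caesarean_births_affected"]] <-
    sum(w$terminal == "birth" & w$affected & w$caesarean)
  e[["n_caesarean_births_unaffected"]] <-
    sum(w$terminal == "birth" & !w$affected & w$caesarean)
  e
}

#' Compare simulated counts with deterministic expectations
#'
#' Per-field z-scores `(observed - expected) / SE` with a binomial-style
#' standard error `sqrt(E (1 - E/n))`; fields with zero expectation get
#' `z = 0` when the observed count is also zero and `Inf` otherwise. Fields
#' with `|z| > 3` are flagged.
#'
#' @param simulated Named event vector from [tabulate_events()].
#' @param expected Named event vector from the deterministic engine run at
#'   cohort size `n`.
#' @param n Number of simulated women.
#' @return A tibble with columns `field`, `observed`, `expected`, `se`, `z`,
#'   `flagged`.
#' @export
compare_to_expectation <- function(simulated, expected, n) {
  fields <- pathway_event_fields()
  if (!all(fields %in% names(simulated)) ||
      !all(fields %in% names(expected))) {
    abort("Both ledgers must contain every pathway event field.")
  }
  obs <- simulated[fields]
  exp_ <- expected[fields]
  se <- sqrt(pmax(exp_ * (1 - exp_ / n), 0))
  z <- ifelse(se > 0, (obs - exp_) / se, ifelse(obs == exp_, 0, Inf))
  tibble::tibble(field = fields, observed = unname(obs),
                 expected = unname(exp_), se = unname(se), z = unname(z),
                 flagged = abs(unname(z)) > 3)
}
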