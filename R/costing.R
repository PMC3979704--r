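#' Cost a pathway event ledger
#'
#' Decomposes a run into the three programme cost components, plus an
#' optional pregnancy-outcome component:
#'
#' * screening: combined tests at GBP 27, quadruple tests at GBP 35, repeat
#'   nuchal-translucency measurements at the configured unit cost;
#' * NIPT: every test (including the repeat after a sample failure) at the
#'   NIPT unit price, plus an optional separate GBP 3 blood draw per taker;
#' * invasive diagnosis: procedures including repeats at GBP 479, with
#'   procedure-related miscarriages costed at GBP 511 and booked under this
#'   component;
#' * pregnancy outcomes (optional): spontaneous losses at GBP 511, TOPs at
#'   GBP 697 (first trimester) or GBP 882 (second), births at GBP 1,341
#'   (vaginal) or GBP 2,436 (caesarean).
#'
#' @param x A `nipt_run` object or named event vector.
#' @param costs A cost schedule (defaults to the one inside the run's
#'   parameters, or [default_parameters()]`$costs`).
#' @param spec A [strategy_spec()] controlling the optional components
#'   (defaults to the run's own).
#' @return A `nipt_costs` object with components `cost_screening`,
#'   `cost_nipt`, `cost_invasive`, `cost_pregnancy_outcomes` (NA when not
#'   included) and `total`, in pounds.
#' @examples
#' run <- run_contingent_nipt(default_parameters())
#' cost_events(run)
#' @export
cost_events <- function(x, costs = NULL, spec = NULL) {
  events <- if (inherits(x, "nipt_run")) x$events else x
  costs <- costs %||%
    (if (inherits(x, "nipt_run")) x$params$costs else default_parameters()$costs)
  spec <- spec %||%
    (if (inherits(x, "nipt_run")) x$spec else strategy_spec("current"))
  e <- events
  cost_screening <- e[["n_screened_t1"]] * costs$combined_test +
    e[["n_screened_t2"]] * costs$quadruple_test +
    e[["n_repeat_nt"]] * costs$repeat_nt
  cost_nipt <- e[["n_nipt_tests"]] * costs$nipt_test +
    if (isTRUE(spec$separate_nipt_blood_draw)) {
      e[["n_nipt_takers"]] * costs$blood_draw
    } else {
      0
    }
  n_misc <- e[["n_procedure_miscarriages_affected"]] +
    e[["n_procedure_miscarriages_unaffected"]]
  cost_invasive <-
    (e[["n_cvs"]] + e[["n_amniocentesis"]] + e[["n_invasive_repeats"]]) *
    costs$invasive_test + n_misc * costs$fetal_loss
  include_outcomes <- isTRUE(spec$include_pregnancy_outcome_costs)
  cost_outcomes <- if (include_outcomes) {
    (e[["n_spontaneous_loss_affected"]] + e[["n_spontaneous_loss_unaffected"]]) *
      costs$fetal_loss +
      e[["n_top_t1"]] * costs$top_first_trimester +
      e[["n_top_t2"]] * costs$top_second_trimester +
      (e[["n_vaginal_births_affected"]] + e[["n_vaginal_births_unaffected"]]) *
      costs$vaginal_birth +
      (e[["n_caesarean_births_affected"]] + e[["n_caesarean_births_unaffected"]]) *
      costs$caesarean_birth
  } else {
    NA_real_
  }
  total <- cost_screening + cost_nipt + cost_invasive +
    if (include_outcomes) cost_outcomes else 0
  structure(
    list(cost_screening = cost_screening,
         cost_nipt = cost_nipt,
         cost_invasive = cost_invasive,
         cost_pregnancy_outcomes = cost_outcomes,
         total = total,
         includes_pregnancy_outcomes = include_outcomes),
    class = "nipt_costs"
  )
}

#' Total cost of a cost summary
#'
#' @param summary A `nipt_costs` object.
#' @param thousands Report in GBP 000s, rounded half-up to the nearest
#'   thousand (the convention of the published cost tables)?
#' @return Total cost in pounds (or GBP 000s).
#' @export
total_cost <- function(summary, thousands = FALSE) {
  stopifnot(inherits(summary, "nipt_costs"))
  if (thousands) round_half_up(summary$total / 1000) else summary$total
}

# round half away from zero (printed tables round 0.5 up; R's round() is
# banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cost one event ledger at several NIPT prices
#'
#' The event counts are price-independent, so the screening and invasive
#' components are constant along the row and the NIPT component is exactly
#' linear in the price.
#'
#' @param x A `nipt_run` or event vector.
#' @param costs Cost schedule (see [cost_events()]).
#' @param nipt_prices Numeric vector of NIPT unit prices in pounds.
#' @param spec Optional [strategy_spec()].
#' @return A list of `nipt_costs`, one per price.
#' @export
cost_grid_row <- function(x, costs = NULL, nipt_prices = c(50, 250, 500, 750),
                          spec = NULL) {
  costs <- costs %||%
    (if (inherits(x, "nipt_run")) x$params$costs else default_parameters()$costs)
  lapply(nipt_prices, function(p) {
    costs$nipt_test <- p
    cost_events(x, costs = costs, spec = spec)
  })
}

#' @export
print.nipt_costs <- function(x, ...) {
  cat("<nipt_costs> (2011/12 GBP)\n")
  cat("  screening: ", format(round(x$cost_screening), big.mark = ","), "\n")
  cat("  NIPT:      ", format(round(x$cost_nipt), big.mark = ","), "\n")
  cat("  invasive:  ", format(round(x$cost_invasive), big.mark = ","), "\n")
  if (x$includes_pregnancy_outcomes) {
    cat("  outcomes:  ", format(round(x$cost_pregnancy_outcomes),
                                big.mark = ","), "\n")
  }
  cat("  total:     ", format(round(x$total), big.mark = ","), "\n")
  invisible(x)
}

#' Tidy a cost summary
#'
#' @param x A `nipt_costs` object.
#' @param ... Unused.
#' @return A tibble with columns `component` and `cost_gbp`.
#' @method tidy nipt_costs
#' @export
tidy.nipt_costs <- function(x, ...) {
  comps <- c(screening = x$cost_screening, nipt = x$cost_nipt,
             invasive = x$cost_invasive)
  if (x$includes_pregnancy_outcomes) {
    comps <- c(comps, pregnancy_outcomes = x$cost_pregnancy_outcomes)
  }
  comps <- c(comps, total = x$total)
  tibble::tibble(component = names(comps), cost_gbp = unname(comps))
}

#' One-row summary of a cost decomposition
#'
#' @param x A `nipt_costs` object.
#' @param ... Unused.
#' @return A one-row tibble in pounds plus the rounded GBP 000s total.
#' @method glance nipt_costs
#' @export
glance.nipt_costs <- function(x, ...) {
  tibble::tibble(
    cost_screening = x$cost_screening,
    cost_nipt = x$cost_nipt,
    cost_invasive = x$cost_invasive,
    cost_pregnancy_outcomes = x$cost_pregnancy_outcomes,
    total = x$total,
    total_thousands = total_cost(x, thousands = TRUE)
  )
}
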