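#' Weekly spontaneous fetal-loss hazard
#'
#' Piecewise-constant weekly hazard of spontaneous loss. Unaffected
#' pregnancies: 0.0012 in weeks 10-25, 0.00034 in weeks 26-40. DS-affected
#' pregnancies: 0.07067 in weeks 10-15, 0.0051 in weeks 16-40.
#'
#' @param params A `nipt_params` bundle.
#' @param status `"affected"` or `"unaffected"`.
#' @param week Gestational week(s) in `[10, 40]`; vectorised.
#' @return Hazard(s) in `[0, 1)`.
#' @export
loss_hazard <- function(params, status = c("affected", "unaffected"), week) {
  status <- match.arg(status)
  if (any(week < 10 | week > 40)) {
    abort("Gestational week must lie in [10, 40].")
  }
  lr <- params$loss_rates
  if (status == "affected") {
    ifelse(week <= 15, lr$affected$weeks_10_15, lr$affected$weeks_16_40)
  } else {
    ifelse(week <= 25, lr$unaffected$weeks_10_25, lr$unaffected$weeks_26_40)
  }
}

#' Probability of surviving between gestational weeks
#'
#' Product over weeks `w` in `[from_week, to_week)` of one minus the weekly
#' hazard, treating each week as an independent survival trial (no
#' within-week proration). The empty interval gives 1.
#'
#' @inheritParams loss_hazard
#' @param from_week,to_week Gestational weeks, `10 <= from_week <= to_week <= 40`.
#' @return Survival probability in `(0, 1]`.
#' @examples
#' p <- default_parameters()
#' survival_probability(p, "unaffected", 10, 15) # (1 - 0.0012)^5
#' @export
survival_probability <- function(params, status, from_week, to_week) {
  if (from_week < 10 || to_week > 40 || from_week > to_week) {
    abort("Require 10 <= from_week <= to_week <= 40.")
  }
  if (from_week == to_week) return(1)
  weeks <- seq(from_week, to_week - 1)
  prod(1 - loss_hazard(params, status, weeks))
}

#' Expected cohort counts at a gestational week
#'
#' @param affected,unaffected Non-negative expected counts.
#' @param week Gestational week in `[10, 40]`.
#' @return A `cohort_slice` object.
#' @export
cohort_slice <- function(affected, unaffected, week) {
  if (affected < 0 || unaffected < 0) abort("Cohort counts must be >= 0.")
  if (week < 10 || week > 40) abort("Gestational week must lie in [10, 40].")
  structure(list(affected = affected, unaffected = unaffected, week = week),
            class = "cohort_slice")
}

#' @export
print.cohort_slice <- function(x, ...) {
  cat("<cohort_slice> week", x$week, "- affected:",
      format(x$affected), "unaffected:", format(x$unaffected), "\n")
  invisible(x)
}

#' Advance a cohort slice to a later week
#'
#' Applies the weekly survival probabilities to both statuses and returns the
#' surviving slice together with the expected spontaneous losses, so that
#' `out + losses = in` exactly.
#'
#' @param slice A [cohort_slice()].
#' @param to_week Target gestational week (`>= slice$week`).
#' @param params A `nipt_params` bundle.
#' @return List with `slice` (at `to_week`) and `losses` (named vector with
#'   `affected`, `unaffected`).
#' @export
advance <- function(slice, to_week, params) {
  if (to_week < slice$week) abort("Cannot advance a cohort backwards in time.")
  sa <- survival_probability(params, "affected", slice$week, to_week)
  su <- survival_probability(params, "unaffected", slice$week, to_week)
  out <- cohort_slice(slice$affected * sa, slice$unaffected * su, to_week)
  losses <- c(affected = slice$affected - out$affected,
              unaffected = slice$unaffected - out$unaffected)
  list(slice = out, losses = losses)
}

#' Packaged maternal-age distribution
#'
#' A synthetic England-like distribution of pregnancies by single year of
#' maternal age (13 through 50, the end bins standing for "13 and under" and
#' "50 and over"). Raw weights follow a unimodal Gaussian-shaped curve centred
#' at 29.7 years, affinely mapped into the band `[0.0024, 0.0165]`; the
#' `proportion` column normalises the weights to sum to 1. The curve is a
#' packaged approximation of national maternity statistics (which are cited
#' by the source model but not reprinted) and can be replaced via
#' [read_age_distribution()].
#'
#' @return A tibble with columns `age`, `weight`, `proportion`.
#' @export
default_age_distribution <- function() {
  age <- 13:50
  shape <- exp(-0.5 * ((age - 29.7) / 5.9)^2)
  weight <- 0.0024 + (0.0165 - 0.0024) * shape
  tibble::tibble(age = age, weight = weight,
                 proportion = weight / sum(weight))
}

#' Read a maternal-age table from CSV
#'
#' Expects exactly the two columns `age,value`; values are normalised to
#' proportions.
#'
#' @param path CSV path.
#' @return A tibble with columns `age`, `weight`, `proportion`.
#' @export
read_age_distribution <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("age", "value"))) {
    abort("Age-distribution CSV must have exactly the columns 'age,value'.")
  }
  if (any(df$value < 0) || sum(df$value) <= 0) {
    abort("Age-distribution values must be non-negative and not all zero.")
  }
  tibble::tibble(age = df$age, weight = df$value,
                 proportion = df$value / sum(df$value))
}

#' Maternal-age-specific Down's syndrome risk at term
#'
#' The standard logistic curve for DS livebirth prevalence by maternal age
#' used throughout the screening literature: risk rises slowly to the
#' mid-thirties and then steeply, from roughly 1 in 1,500 at age 20 to about
#' 1 in 30 at 45.
#'
#' @param age Maternal age(s) in years.
#' @return Term risk(s) as proportions.
#' @export
ds_term_risk <- function(age) {
  1 / (1 + exp(7.330 - 4.211 / (1 + exp(-0.282 * (age - 37.23)))))
}

#' Build the prevalence model
#'
#' DS prevalence as a function of maternal age and gestational week. The
#' age-specific term risks are converted to week-10 risks by inverse survival
#' under the fetal-loss hazards (DS-affected pregnancies are lost faster, so
#' prevalence among ongoing pregnancies falls with gestation), scaled by a
#' single factor so that the cohort-average week-10 prevalence equals
#' `params$prevalence$week10_cohort_prevalence`, and clamped into the band
#' `[0.001, 0.026]`. The packaged term-risk curve is an approximation of the
#' cited (but unprinted) national prevalence tables and can be replaced via
#' `term_risk_table`.
#'
#' @param params A `nipt_params` bundle.
#' @param ages Age distribution tibble (see [default_age_distribution()]).
#' @param term_risk_table Optional tibble with columns `age`, `value` giving
#'   term risks; defaults to [ds_term_risk()] evaluated on `ages$age`.
#' @return A `nipt_prevalence` object: tibble of `age`, `proportion`,
#'   `term_risk`, `week10_risk` plus the loss model needed to evaluate
#'   [prevalence_at()].
#' @export
prevalence_model <- function(params, ages = default_age_distribution(),
                             term_risk_table = NULL) {
  target <- params$prevalence$week10_cohort_prevalence
  term <- if (is.null(term_risk_table)) {
    ds_term_risk(ages$age)
  } else {
    if (!all(c("age", "value") %in% names(term_risk_table))) {
      abort("term_risk_table must have columns 'age' and 'value'.")
    }
    approx(term_risk_table$age, term_risk_table$value, xout = ages$age,
           rule = 2)$y
  }
  s_aff <- survival_probability(params, "affected", 10, 40)
  s_un <- survival_probability(params, "unaffected", 10, 40)
  # week-10 risk implied by a term risk q40: among pregnancies alive at week
  # 10, q10 s_aff survive affected and (1 - q10) s_un survive unaffected
  q10_of <- function(q40) q40 * s_un / (s_aff + q40 * (s_un - s_aff))
  clamp <- function(q) pmin(pmax(q, 0.001), 0.026)
  cohort_prev <- function(k) {
    sum(ages$proportion * clamp(q10_of(pmin(k * term, 0.999))))
  }
  k <- uniroot(function(k) cohort_prev(k) - target,
               lower = 1e-4, upper = 50, tol = 1e-12)$root
  week10 <- clamp(q10_of(pmin(k * term, 0.999)))
  structure(
    list(table = tibble::tibble(age = ages$age,
                                proportion = ages$proportion,
                                term_risk = term,
                                week10_risk = week10),
         scale = k,
         params = params),
    class = "nipt_prevalence"
  )
}

#' Evaluate the prevalence surface
#'
#' Prevalence among ongoing pregnancies of a given maternal age at a given
#' gestational week, obtained by propagating the week-10 risk forward under
#' the differential loss hazards and clamping into `[0.001, 0.026]`.
#' Non-increasing in week for fixed age.
#'
#' @param prev A `nipt_prevalence` object.
#' @param age Maternal age(s).
#' @param week Gestational week in `[10, 40]`.
#' @return Prevalence proportion(s).
#' @export
prevalence_at <- function(prev, age, week) {
  params <- prev$params
  q10 <- approx(prev$table$age, prev$table$week10_risk, xout = age,
                rule = 2)$y
  sa <- survival_probability(params, "affected", 10, week)
  su <- survival_probability(params, "unaffected", 10, week)
  qw <- q10 * sa / (q10 * sa + (1 - q10) * su)
  pmin(pmax(qw, 0.001), 0.026)
}

#' @export
print.nipt_prevalence <- function(x, ...) {
  cat("<nipt_prevalence> cohort week-10 prevalence:",
      format(sum(x$table$proportion * x$table$week10_risk), digits = 4),
      "(scale", format(x$scale, digits = 4), ")\n")
  invisible(x)
}

#' Initial screening cohort at week 10
#'
#' Splits the cohort into expected DS-affected and unaffected pregnancies at
#' gestational week 10 using the age distribution and prevalence model;
#' `affected + unaffected = cohort_size` exactly.
#'
#' @param params A `nipt_params` bundle.
#' @param ages Age distribution tibble.
#' @param prev A `nipt_prevalence` object (built from `params` if `NULL`).
#' @return A [cohort_slice()] at week 10.
#' @export
initial_cohort <- function(params, ages = default_age_distribution(),
                           prev = NULL) {
  if (is.null(prev)) prev <- prevalence_model(params, ages)
  p_aff <- sum(ages$proportion * approx(prev$table$age,
                                        prev$table$week10_risk,
                                        xout = ages$age, rule = 2)$y)
  affected <- params$cohort_size * p_aff
  cohort_slice(affected, params$cohort_size - affected, 10)
}
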