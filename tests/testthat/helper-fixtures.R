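# Shared fixtures: all built in code at test time.

# A random but valid parameter bundle. Loss hazards are kept in clinically
# plausible ranges so week-long survival products stay well-conditioned.
random_parameters <- function() {
  dr <- 0.5 + cumsum(runif(4, 0.02, 0.1))
  fpr <- 0.01 + cumsum(runif(4, 0.01, 0.05))
  overrides <- list(
    screening = list(
      combined = list(
        `150` = list(detection_rate = dr[1], false_positive_rate = fpr[1]),
        `500` = list(detection_rate = dr[2], false_positive_rate = fpr[2]),
        `1000` = list(detection_rate = dr[3], false_positive_rate = fpr[3]),
        `2000` = list(detection_rate = dr[4], false_positive_rate = fpr[4])
      ),
      quadruple = list(detection_rate = runif(1, 0.5, 0.95),
                       false_positive_rate = runif(1, 0.01, 0.2)),
      nt_failure = list(first_rate = runif(1, 0.05, 0.2),
                        last_rate = runif(1, 0.2, 0.3))
    ),
    invasive = list(
      cvs = list(detection_rate = runif(1, 0.8, 1),
                 sample_failure_rate = runif(1, 0, 0.05),
                 procedure_miscarriage_rate = runif(1, 0, 0.02)),
      amniocentesis = list(detection_rate = runif(1, 0.8, 1),
                           sample_failure_rate = runif(1, 0, 0.05),
                           procedure_miscarriage_rate = runif(1, 0, 0.02))
    ),
    nipt = list(detection_rate = runif(1, 0.9, 1),
                false_positive_rate = runif(1, 0, 0.05),
                sample_failure_rate = runif(1, 0, 0.1),
                procedure_miscarriage_rate = 0),
    loss_rates = list(
      unaffected = list(weeks_10_25 = runif(1, 5e-4, 3e-3),
                        weeks_26_40 = runif(1, 1e-4, 1e-3)),
      affected = list(weeks_10_15 = runif(1, 0.01, 0.09),
                      weeks_16_40 = runif(1, 1e-3, 1e-2))
    ),
    uptakes = list(
      screening = runif(1), late_arrival = runif(1, 0, 0.5),
      invasive_unaffected = runif(1), invasive_affected = runif(1),
      nipt_unaffected = runif(1), nipt_affected = runif(1),
      nipt_firstline = runif(1), top = runif(1)
    ),
    birth_mode = local({
      v <- runif(1)
      list(vaginal = v, caesarean = 1 - v)
    })
  )
  load_parameters(overrides)
}

# A random week-10 cohort split summing exactly to the cohort size.
random_cohort <- function(size = 10000) {
  affected <- runif(1, 0, 300)
  cohort_slice(affected, size - affected, 10)
}

# A hand-filled event ledger for costing arithmetic.
manual_events <- function(...) {
  e <- setNames(numeric(length(pathway_event_fields())),
                pathway_event_fields())
  overrides <- list(...)
  e[names(overrides)] <- unlist(overrides)
  e
}

run_all_strategies <- function(params, cohort = NULL) {
  list(
    current = run_current_screening(params, cohort = cohort),
    contingent = run_contingent_nipt(params, cohort = cohort),
    firstline = run_firstline_nipt(params, cohort = cohort)
  )
}
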