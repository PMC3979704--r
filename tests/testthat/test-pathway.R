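p <- default_parameters()

test_that("screening stage splits takers by the printed rates", {
  slice <- cohort_slice(10, 990, 12)
  perf <- list(detection_rate = 0.85, false_positive_rate = 0.025)
  res <- apply_screening(slice, perf, uptake = 1)
  expect_equal(unname(res$positives), c(8.5, 24.75))
  # conservation across the four outputs
  expect_equal(sum(res$positives) + sum(res$negatives) +
                 res$decliners$affected + res$decliners$unaffected,
               1000)
  none <- apply_screening(slice, perf, uptake = 0)
  expect_equal(none$decliners$affected, 10)
  expect_equal(none$decliners$unaffected, 990)
  expect_equal(sum(none$positives), 0)
  perfect <- apply_screening(slice, list(detection_rate = 0.85,
                                         false_positive_rate = 0), 1)
  expect_equal(perfect$positives[["unaffected"]], 0)
})

test_that("NIPT stage repeats failed samples once at full test count", {
  nipt <- default_parameters()$nipt
  res <- apply_nipt(c(affected = 0, unaffected = 100), nipt, uptake = 1)
  expect_equal(res$nipt_tests, 105)
  res2 <- apply_nipt(c(affected = 10, unaffected = 0), nipt, uptake = 1)
  expect_equal(res2$positives[["affected"]], 9.9)
  res3 <- apply_nipt(c(affected = 10, unaffected = 100), nipt, uptake = 0)
  expect_equal(res3$nipt_tests, 0)
  expect_equal(sum(res3$decliners), 110)
  # conservation by status
  res4 <- apply_nipt(c(affected = 7, unaffected = 31), nipt,
                     c(affected = 0.9, unaffected = 0.8))
  expect_equal(res4$positives[["affected"]] + res4$negatives[["affected"]] +
                 res4$decliners[["affected"]], 7)
  expect_equal(res4$positives[["unaffected"]] + res4$negatives[["unaffected"]] +
                 res4$decliners[["unaffected"]], 31)
})

test_that("invasive stage books uptake, repeats and procedural losses", {
  cvs <- default_parameters()$invasive$cvs
  res <- apply_invasive(c(affected = 10, unaffected = 3), cvs,
                        c(affected = 0.9, unaffected = 0.8))
  expect_equal(res$n_invasive, 9 + 2.4)
  expect_equal(res$n_repeats, 11.4 * 0.013)
  expect_equal(sum(res$n_miscarriages), 11.4 * 0.005)
  # a DS pregnancy miscarried by the procedure is not detected
  expect_equal(res$confirmed_ds, 9 * (1 - 0.005))
  expect_lt(res$confirmed_ds, 9)
  # imperfect test leaves undetected takers in the flow
  res2 <- apply_invasive(c(affected = 10, unaffected = 0),
                         list(detection_rate = 0.8, sample_failure_rate = 0,
                              procedure_miscarriage_rate = 0), 1)
  expect_equal(res2$confirmed_ds, 8)
  expect_equal(res2$undetected_affected, 2)
})

test_that("termination uptake and birth-mode split follow the printed rates", {
  res <- apply_top_and_births(10, cohort_slice(0, 0, 13), p,
                              diagnosis_week = 13)
  expect_equal(res$n_top_t1, 9.21)
  expect_equal(res$n_top_t2, 0)
  late <- apply_top_and_births(10, cohort_slice(0, 0, 17), p,
                               diagnosis_week = 17)
  expect_equal(late$n_top_t2, 9.21)
  # full TOP uptake leaves no affected births among the confirmed
  p_top <- load_parameters(list(uptakes = list(top = 1)))
  all_top <- apply_top_and_births(10, cohort_slice(0, 0, 13), p_top, 13)
  expect_equal(unname(all_top$births[c("vaginal_affected",
                                       "caesarean_affected")]), c(0, 0))
  # unaffected at week 17 deliver after surviving to week 40
  res_u <- apply_top_and_births(0, cohort_slice(0, 100, 17), p, 17)
  s <- survival_probability(p, "unaffected", 17, 40)
  expect_equal(res_u$births[["vaginal_unaffected"]], 100 * s * 0.752)
})

test_that("zero uptake collapses each strategy to a no-testing cohort", {
  p0 <- load_parameters(list(uptakes = list(screening = 0)))
  run0 <- run_current_screening(p0)
  expect_equal(sum(run0$events[c("n_screened_t1", "n_screened_t2",
                                 "n_repeat_nt", "n_cvs", "n_amniocentesis",
                                 "n_ds_detected")]), 0)
  expect_lt(max(conservation_error(run0)), 1e-9)

  p1 <- load_parameters(list(uptakes = list(nipt_unaffected = 0,
                                            nipt_affected = 0)))
  run1 <- run_contingent_nipt(p1)
  expect_equal(sum(run1$events[c("n_nipt_takers", "n_nipt_tests", "n_cvs",
                                 "n_amniocentesis", "n_ds_detected")]), 0)

  p2 <- load_parameters(list(uptakes = list(nipt_firstline = 0)))
  run2 <- run_firstline_nipt(p2)
  testing_fields <- setdiff(pathway_event_fields(),
                            c("n_spontaneous_loss_affected",
                              "n_spontaneous_loss_unaffected",
                              "n_vaginal_births_affected",
                              "n_vaginal_births_unaffected",
                              "n_caesarean_births_affected",
                              "n_caesarean_births_unaffected"))
  expect_equal(sum(abs(run2$events[testing_fields])), 0)
  expect_lt(max(conservation_error(run2)), 1e-9)
})

test_that("default runs conserve the cohort and satisfy ledger identities", {
  runs <- run_all_strategies(p)
  for (run in runs) {
    expect_lt(max(conservation_error(run)), 1e-9)
    e <- run$events
    # miscarriages proportional to invasive tests with factor exactly 0.005
    expect_equal(e[["n_procedure_miscarriages_affected"]] +
                   e[["n_procedure_miscarriages_unaffected"]],
                 (e[["n_cvs"]] + e[["n_amniocentesis"]]) * 0.005)
    # detection never exceeds the affected pool at week 10
    expect_lte(e[["n_ds_detected"]], run$cohort$affected)
  }
  # NIPT columns are structurally zero under current screening
  expect_equal(summarize_outcomes(runs$current)$n_nipt, 0)
  expect_equal(summarize_outcomes(runs$current)$n_nipt_positive, 0)
  # first-line runs have no conventional screening
  expect_equal(summarize_outcomes(runs$firstline)$n_screened, 0)
})

test_that("outcome orderings match the published pattern", {
  cutoffs <- c(150, 500, 1000, 2000)
  sweeps <- lapply(cutoffs, function(co) {
    summarize_outcomes(run_contingent_nipt(p, cutoff = co))
  })
  detected <- vapply(sweeps, `[[`, 0, "n_ds_detected")
  nipt_takers <- vapply(sweeps, `[[`, 0, "n_nipt")
  expect_true(all(diff(detected) > 0))
  expect_true(all(diff(nipt_takers) > 0))

  cur <- summarize_outcomes(run_current_screening(p, cutoff = 150))
  con <- sweeps[[1]]
  fl <- summarize_outcomes(run_firstline_nipt(p))
  expect_gt(fl$n_ds_detected, con$n_ds_detected)
  expect_gt(con$n_ds_detected, 0)
  expect_lt(con$n_procedure_miscarriages, cur$n_procedure_miscarriages)
})

test_that("uptake-scenario runs detect more cases than the base case", {
  base <- summarize_outcomes(
    run_strategy(p, strategy_spec("contingent_nipt", 150)))
  full <- summarize_outcomes(
    run_strategy(p, strategy_spec("contingent_nipt", 150,
                                  uptake_scenario = "nipt_100")))
  expect_gt(full$n_ds_detected, base$n_ds_detected)
  expect_gt(full$n_nipt, base$n_nipt)

  fl_base <- summarize_outcomes(run_strategy(p, strategy_spec("firstline_nipt")))
  fl_79 <- summarize_outcomes(
    run_strategy(p, strategy_spec("firstline_nipt",
                                  uptake_scenario = "firstline_79")))
  expect_gt(fl_79$n_ds_detected, fl_base$n_ds_detected)
})

test_that("summaries and tidiers expose the ledger faithfully", {
  run <- run_contingent_nipt(p)
  long <- tidy(run)
  expect_setequal(long$event, pathway_event_fields())
  g <- glance(run)
  expect_equal(g$n_invasive,
               run$events[["n_invasive_affected"]] +
                 run$events[["n_invasive_unaffected"]])
  zeros <- summarize_outcomes(setNames(numeric(length(pathway_event_fields())),
                                       pathway_event_fields()))
  expect_equal(zeros$n_ds_detected, 0)
  expect_equal(zeros$n_screened, 0)
})
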