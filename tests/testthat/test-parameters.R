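test_that("defaults carry the published model inputs as proportions", {
  p <- default_parameters()
  expect_equal(p$nipt$detection_rate, 0.99)
  expect_equal(p$nipt$false_positive_rate, 0.01)
  expect_equal(p$nipt$sample_failure_rate, 0.05)
  expect_equal(p$nipt$procedure_miscarriage_rate, 0)
  expect_equal(p$costs$invasive_test, 479)
  expect_equal(p$uptakes$top, 0.921)
  expect_equal(p$uptakes$screening, 0.69)
  expect_equal(p$uptakes$late_arrival, 0.15)
  expect_equal(
    unname(vapply(p$screening$combined, `[[`, 0, "detection_rate")),
    c(0.85, 0.94, 0.96, 0.98))
  expect_equal(
    unname(vapply(p$screening$combined, `[[`, 0, "false_positive_rate")),
    c(0.025, 0.07, 0.12, 0.19))
  expect_equal(p$screening$quadruple$detection_rate, 0.805)
  expect_equal(p$invasive$cvs$sample_failure_rate, 0.013)
  expect_equal(p$invasive$amniocentesis$sample_failure_rate, 0.008)
  expect_equal(p$loss_rates$unaffected$weeks_10_25, 0.0012)
  expect_equal(p$loss_rates$affected$weeks_10_15, 0.07067)
  # identical across calls
  expect_identical(unclass(default_parameters()), unclass(p))
  # every packaged combined-test DR exceeds its FPR
  for (perf in p$screening$combined) {
    expect_gt(perf$detection_rate, perf$false_positive_rate)
  }
})

test_that("loading merges overrides onto defaults and validates bounds", {
  expect_identical(unclass(load_parameters(NULL)),
                   unclass(default_parameters()))
  expect_identical(unclass(load_parameters(list())),
                   unclass(default_parameters()))

  p <- load_parameters(list(uptakes = list(screening = 0.79)))
  expect_equal(p$uptakes$screening, 0.79)
  ref <- default_parameters()
  p$uptakes$screening <- ref$uptakes$screening
  expect_identical(unclass(p), unclass(ref))

  expect_error(load_parameters(list(uptakes = list(screening = 1.2))),
               "uptakes.screening")
  expect_error(load_parameters(list(costs = list(nipt_test = -5))),
               "costs.nipt_test")
  expect_error(load_parameters(list(uptakes = list(typo_key = 0.5))),
               "Unknown configuration key")
  expect_error(load_parameters(list(screening = list(combined = list(
    `300` = list(detection_rate = 0.9, false_positive_rate = 0.05))))),
    "Unknown configuration key")
})

test_that("YAML serialisation round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- load_parameters(list(costs = list(nipt_test = 250),
                            uptakes = list(nipt_firstline = 0.79)))
  write_parameters(p, path)
  expect_identical(unclass(load_parameters(path)), unclass(p))

  # every probability-typed field of a validated bundle lies in [0, 1],
  # every cost is non-negative
  flat <- tidy(p)
  costs <- flat$value[grepl("^costs\\.", flat$key)]
  expect_true(all(costs >= 0))
  probs <- flat$value[grepl("rate|uptake|vaginal|caesarean|prevalence",
                            flat$key) & !grepl("^costs\\.", flat$key)]
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("scenario presets reproduce the published uptake variants", {
  base <- scenario_presets("base_contingent")
  expect_identical(base$overrides, list())
  expect_equal(default_parameters()$uptakes$nipt_unaffected, 0.80)
  expect_equal(default_parameters()$uptakes$nipt_affected, 0.90)

  full <- scenario_presets("nipt_100")
  p <- load_parameters(full$overrides)
  expect_equal(p$uptakes$nipt_unaffected, 1)
  expect_equal(p$uptakes$nipt_affected, 1)

  both <- load_parameters(scenario_presets("nipt_100_screen_79")$overrides)
  expect_equal(both$uptakes$screening, 0.79)
  expect_equal(both$uptakes$nipt_unaffected, 1)

  fl <- scenario_presets("firstline_79")
  expect_equal(load_parameters(fl$overrides)$uptakes$nipt_firstline, 0.79)
  expect_equal(fl$spec$strategy, "firstline_nipt")

  expect_error(scenario_presets("no_such_scenario"), "Unknown scenario")
})

test_that("strategy specification rejects unknown cut-offs", {
  expect_error(strategy_spec("current", cutoff = 300), "cut-off")
  expect_true(is.na(strategy_spec("firstline_nipt", cutoff = 300)$cutoff))
})

test_that("NT failure rate interpolates within the printed 14-19% range", {
  p <- default_parameters()
  weeks <- seq(10, 16, by = 0.5)
  rates <- vapply(weeks, function(w) nt_failure_rate(p, w), 0)
  expect_true(all(rates >= 0.14 & rates <= 0.19))
  expect_equal(nt_failure_rate(p, 11), 0.14)
  expect_equal(nt_failure_rate(p, 14), 0.19)
  expect_lt(nt_failure_rate(p, 12), nt_failure_rate(p, 13))
})
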