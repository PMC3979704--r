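p <- default_parameters()
contingent <- strategy_spec("contingent_nipt", cutoff = 150)

test_that("simulated trajectories are reproducible and grow stably", {
  w1 <- simulate_women(p, contingent, n = 500, seed = 7)
  w2 <- simulate_women(p, contingent, n = 500, seed = 7)
  expect_identical(w1, w2)
  w3 <- simulate_women(p, contingent, n = 800, seed = 7)
  # per-woman substreams: earlier women unchanged when n grows
  expect_identical(w1, w3[1:500, ])
  w4 <- simulate_women(p, contingent, n = 500, seed = 8)
  expect_false(identical(w1, w4))
})

test_that("zero uptake sends every woman to delivery or spontaneous loss", {
  p0 <- load_parameters(list(uptakes = list(screening = 0,
                                            nipt_firstline = 0)))
  for (spec in list(strategy_spec("current"),
                    strategy_spec("firstline_nipt"))) {
    w <- simulate_women(p0, spec, n = 2000, seed = 11)
    expect_true(all(w$terminal %in% c("birth", "spontaneous_loss")))
    expect_equal(sum(w$screened), 0)
    expect_equal(sum(w$nipt_taken), 0)
    expect_equal(sum(w$invasive_taken), 0)
  }
})

test_that("trajectories respect pathway ordering and one terminal state", {
  w <- simulate_women(p, contingent, n = 20000, seed = 3)
  # stage implications
  expect_true(all(!w$screen_positive | w$screened))
  expect_true(all(!w$nipt_taken | w$screen_positive))
  expect_true(all(!w$nipt_positive | w$nipt_taken))
  expect_true(all(!w$invasive_taken | w$nipt_positive))
  expect_true(all(!w$ds_detected | (w$invasive_taken & w$affected)))
  expect_true(all(!w$top | w$ds_detected))
  # no one both miscarries and delivers
  expect_true(all(table(w$terminal) >= 0))
  expect_equal(nrow(w), 20000)
  e <- tabulate_events(w)
  total_terminal <- e[["n_spontaneous_loss_affected"]] +
    e[["n_spontaneous_loss_unaffected"]] +
    e[["n_procedure_miscarriages_affected"]] +
    e[["n_procedure_miscarriages_unaffected"]] +
    e[["n_top_t1"]] + e[["n_top_t2"]] +
    e[["n_vaginal_births_affected"]] + e[["n_vaginal_births_unaffected"]] +
    e[["n_caesarean_births_affected"]] + e[["n_caesarean_births_unaffected"]]
  expect_equal(total_terminal, 20000)
  # no NIPT events under the current strategy
  wc <- simulate_women(p, strategy_spec("current"), n = 5000, seed = 5)
  expect_equal(sum(wc$nipt_taken), 0)
  expect_gt(sum(wc$invasive_taken), 0)
})

test_that("a hand-built trajectory table tabulates by inspection", {
  women <- tibble::tibble(
    maternal_age = c(30, 41, 25),
    affected = c(FALSE, TRUE, FALSE),
    booking = c("first", "first", "second"),
    screened = c(TRUE, TRUE, FALSE),
    nt_repeat = c(TRUE, FALSE, FALSE),
    screen_positive = c(FALSE, TRUE, FALSE),
    nipt_taken = c(FALSE, TRUE, FALSE),
    nipt_test_repeat = c(FALSE, TRUE, FALSE),
    nipt_positive = c(FALSE, TRUE, FALSE),
    invasive_taken = c(FALSE, TRUE, FALSE),
    invasive_type = c(NA, "cvs", NA),
    invasive_repeat = c(FALSE, FALSE, FALSE),
    procedure_miscarriage = c(FALSE, FALSE, FALSE),
    ds_detected = c(FALSE, TRUE, FALSE),
    top = c(FALSE, TRUE, FALSE),
    top_trimester = c(NA_integer_, 1L, NA_integer_),
    terminal = c("birth", "top", "spontaneous_loss"),
    caesarean = c(TRUE, FALSE, FALSE)
  )
  e <- tabulate_events(women)
  expect_equal(e[["n_screened_t1"]], 2)
  expect_equal(e[["n_screened_t2"]], 0)
  expect_equal(e[["n_repeat_nt"]], 1)
  expect_equal(e[["n_nipt_tests"]], 2) # one test plus one repeat
  expect_equal(e[["n_cvs"]], 1)
  expect_equal(e[["n_ds_detected"]], 1)
  expect_equal(e[["n_top_t1"]], 1)
  expect_equal(e[["n_caesarean_births_unaffected"]], 1)
  expect_equal(e[["n_spontaneous_loss_unaffected"]], 1)
  expect_equal(sum(tabulate_events(women[0, ])), 0)
})

test_that("moderate-n simulations show no systematic drift", {
  n <- 60000
  w <- simulate_women(p, contingent, n = n, seed = 123)
  sim <- tabulate_events(w)
  p_n <- default_parameters()
  p_n$cohort_size <- n
  expected <- run_contingent_nipt(p_n)$events
  cmp <- compare_to_expectation(sim, expected, n)
  expect_true(all(is.finite(cmp$z)))
  expect_lt(max(abs(cmp$z)), 4)
  # identical ledgers give all-zero z-scores
  self <- compare_to_expectation(expected, expected, n)
  expect_true(all(self$z == 0))
})

test_that("an injected rate corruption is flagged by the z diagnostic", {
  n <- 50000
  corrupted <- default_parameters()
  corrupted$nipt$false_positive_rate <- 2 * corrupted$nipt$false_positive_rate
  w <- simulate_women(corrupted, strategy_spec("firstline_nipt"),
                      n = n, seed = 99)
  sim <- tabulate_events(w)
  clean <- default_parameters()
  clean$cohort_size <- n
  expected <- run_firstline_nipt(clean)$events
  cmp <- compare_to_expectation(sim, expected, n)
  expect_gt(cmp$z[cmp$field == "n_nipt_positive_unaffected"], 3)
})
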