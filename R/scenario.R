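#' Run the full scenario grid
#'
#' Evaluates every requested strategy at every screening risk cut-off, costs
#' each event ledger at every NIPT unit price, and stacks the results into
#' one tidy tibble. The current-screening strategy is price-independent and
#' appears once per cut-off with `nipt_price = NA`; first-line NIPT has no
#' cut-off. Results are a pure function of the inputs: reruns are identical.
#'
#' @param params A `nipt_params` bundle.
#' @param strategies Character vector from `c("current", "contingent_nipt",
#'   "firstline_nipt")`.
#' @param cutoffs Risk cut-off denominators for strategies with screening.
#' @param prices NIPT unit prices in pounds.
#' @param scenarios Uptake-scenario names (see [scenario_presets()];
#'   `"base"` applies no overrides).
#' @param include_pregnancy_outcome_costs,separate_nipt_blood_draw Passed to
#'   [strategy_spec()].
#' @return A `nipt_grid` tibble: one row per (scenario, strategy, cut-off,
#'   price) cell with the outcome columns and the cost decomposition in
#'   pounds.
#' @examples
#' grid <- run_grid(default_parameters(), strategies = "contingent_nipt",
#'                  cutoffs = 150, prices = c(50, 500))
#' @export
run_grid <- function(params,
                     strategies = c("current", "contingent_nipt",
                                    "firstline_nipt"),
                     cutoffs = c(150, 500, 1000, 2000),
                     prices = c(50, 250, 500, 750),
                     scenarios = "base",
                     include_pregnancy_outcome_costs = FALSE,
                     separate_nipt_blood_draw = FALSE) {
  if (length(strategies) == 0 || length(cutoffs) == 0 || length(prices) == 0 ||
      length(scenarios) == 0) {
    abort("All grid axes must be non-empty.")
  }
  bad <- setdiff(strategies,
                 c("current", "contingent_nipt", "firstline_nipt"))
  if (length(bad)) abort(paste0("Unknown strategy: ", bad[1], "."))

  cells <- purrr::map_dfr(scenarios, function(sc) {
    dplyr::bind_rows(purrr::map_dfr(strategies, function(st) {
      if (st == "firstline_nipt") {
        tibble::tibble(scenario = sc, strategy = st, cutoff = NA_real_)
      } else {
        tibble::tibble(scenario = sc, strategy = st, cutoff = cutoffs)
      }
    }))
  })

  rows <- purrr::pmap_dfr(cells, function(scenario, strategy, cutoff) {
    spec <- strategy_spec(
      strategy,
      cutoff = if (is.na(cutoff)) 150 else cutoff,
      uptake_scenario = scenario,
      include_pregnancy_outcome_costs = include_pregnancy_outcome_costs,
      separate_nipt_blood_draw = separate_nipt_blood_draw
    )
    run <- run_strategy(params, spec)
    out <- summarize_outcomes(run)
    row_prices <- if (strategy == "current") NA_real_ else prices
    costs <- cost_grid_row(run,
                           nipt_prices = ifelse(is.na(row_prices), 0,
                                                row_prices),
                           spec = spec)
    purrr::map_dfr(seq_along(row_prices), function(i) {
      cs <- costs[[i]]
      tibble::tibble(
        scenario = scenario, strategy = strategy, cutoff = cutoff,
        nipt_price = row_prices[i],
        n_screened = out$n_screened,
        n_nipt = if (strategy == "current") 0 else out$n_nipt,
        n_nipt_positive = if (strategy == "current") 0 else out$n_nipt_positive,
        n_invasive = out$n_invasive,
        n_procedure_miscarriages = out$n_procedure_miscarriages,
        n_ds_detected = out$n_ds_detected,
        cost_screening = cs$cost_screening,
        cost_nipt = cs$cost_nipt,
        cost_invasive = cs$cost_invasive,
        cost_pregnancy_outcomes = cs$cost_pregnancy_outcomes,
        total_cost = cs$total
      )
    })
  })
  class(rows) <- c("nipt_grid", class(rows))
  rows
}

#' Write grid results to report files
#'
#' Emits `outcomes.csv` (counts to 2 decimal places) and `costs.csv`
#' (GBP 000s, rounded half-up) shaped like the published outcome and cost
#' tables, each preceded by a `#`-comment metadata block, plus
#' `results.json`, a machine-readable sidecar holding the exact unrounded
#' values.
#'
#' @param results A `nipt_grid` tibble from [run_grid()].
#' @param destination Directory to write into (created if missing).
#' @param metadata Optional named character vector embedded in the CSV
#'   header comments (e.g. seed, package version).
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(results, destination, metadata = NULL) {
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  header <- c(
    paste0("# generated by niptscreen ",
           as.character(utils::packageVersion("niptscreen"))),
    if (!is.null(metadata)) paste0("# ", names(metadata), ": ", metadata)
  )
  outcome_cols <- c("scenario", "strategy", "cutoff", "nipt_price",
                    "n_screened", "n_nipt", "n_nipt_positive", "n_invasive",
                    "n_procedure_miscarriages", "n_ds_detected")
  outcomes <- unique(dplyr::mutate(
    results[, outcome_cols],
    dplyr::across(dplyr::starts_with("n_"), ~ round_half_up(.x, 2))
  )[, setdiff(outcome_cols, "nipt_price")])
  costs <- dplyr::mutate(
    results[, c("scenario", "strategy", "cutoff", "nipt_price",
                "cost_screening", "cost_nipt", "cost_invasive",
                "cost_pregnancy_outcomes", "total_cost")],
    dplyr::across(dplyr::starts_with("cost_") | dplyr::matches("total_cost"),
                  ~ round_half_up(.x / 1000))
  )

  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    write.csv(df, con, row.names = FALSE)
  }
  files <- c(
    outcomes = file.path(destination, "outcomes.csv"),
    costs = file.path(destination, "costs.csv"),
    sidecar = file.path(destination, "results.json")
  )
  write_with_header(outcomes, files[["outcomes"]])
  write_with_header(costs, files[["costs"]])
  jsonlite::write_json(as.data.frame(results), files[["sidecar"]],
                       digits = NA, na = "null")
  invisible(files)
}

#' Plot total cost against NIPT price across the grid
#'
#' @param object A `nipt_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object: total cost (GBP 000s) versus NIPT unit price,
#'   one line per strategy/cut-off, with the price-independent current
#'   programme as a horizontal reference.
#' @method autoplot nipt_grid
#' @export
autoplot.nipt_grid <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    label = paste0(.data$strategy,
                   ifelse(is.na(.data$cutoff), "",
                          paste0(" 1:", .data$cutoff))),
    total_k = .data$total_cost / 1000
  )
  priced <- dplyr::filter(df, !is.na(.data$nipt_price))
  flat <- dplyr::filter(df, is.na(.data$nipt_price))
  gg <- ggplot2::ggplot(priced,
                        ggplot2::aes(x = .data$nipt_price, y = .data$total_k,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "NIPT unit price (GBP)",
                  y = "Total cost (GBP 000s)", colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(flat)) {
    gg <- gg + ggplot2::geom_hline(
      data = flat, ggplot2::aes(yintercept = .data$total_k),
      linetype = "dashed")
  }
  gg
}
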