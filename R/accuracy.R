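#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (integer, `0 <= successes <= n`).
#' @param n Number of trials (positive integer).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(low, high)` of proportions containing the point
#'   estimate.
#' @examples
#' wilson_interval(736, 741)
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n) {
    abort("Require 0 <= successes <= n with n > 0.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary counts give exact bounds (the algebraic limit), avoiding
  # floating-point excursions past the point estimate
  c(low = if (successes == 0) 0 else max(0, centre - half),
    high = if (successes == n) 1 else min(1, centre + half))
}

#' Sensitivity and specificity from a 2x2 validity table
#'
#' Point estimates with 95% Wilson score intervals, reported as percentages:
#' sensitivity `100 * tp / (tp + fn)`, specificity `100 * tn / (tn + fp)`.
#'
#' @param study A one-row data frame (or list) with integer counts `tp`,
#'   `fn`, `tn`, `fp`; optional `study` and `approach` labels.
#' @param level Confidence level for the score intervals.
#' @return A one-row tibble with columns `study`, `approach`, `tp`, `fn`,
#'   `tn`, `fp`, `sensitivity`, `sens_low`, `sens_high`, `specificity`,
#'   `spec_low`, `spec_high` (all percentages).
#' @examples
#' accuracy_from_counts(list(tp = 212, fn = 3, tn = 1471, fp = 3))
#' @export
accuracy_from_counts <- function(study, level = 0.95) {
  tp <- study$tp; fn <- study$fn; tn <- study$tn; fp <- study$fp
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    abort("Counts tp, fn, tn, fp must be non-negative integers.")
  }
  if (tp + fn == 0) {
    abort("Sensitivity undefined: tp + fn must be positive.")
  }
  if (tn + fp == 0) {
    abort("Specificity undefined: tn + fp must be positive.")
  }
  sens_ci <- wilson_interval(tp, tp + fn, level)
  spec_ci <- wilson_interval(tn, tn + fp, level)
  label <- as.character(study$study %||% NA_character_)
  approach <- as.character(study$approach %||% NA_character_)
  tibble::tibble(
    study = label,
    approach = approach,
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = 100 * tp / (tp + fn),
    sens_low = 100 * sens_ci[["low"]],
    sens_high = 100 * sens_ci[["high"]],
    specificity = 100 * tn / (tn + fp),
    spec_low = 100 * spec_ci[["low"]],
    spec_high = 100 * spec_ci[["high"]]
  )
}

#' Per-study accuracy for a table of validity studies
#'
#' @param studies Data frame with one row per study and columns `tp`, `fn`,
#'   `tn`, `fp` (optionally `study`, `approach`).
#' @param level Confidence level.
#' @return A `nipt_accuracy` tibble, one row per study.
#' @export
accuracy_table <- function(studies, level = 0.95) {
  out <- purrr::map_dfr(seq_len(nrow(studies)), function(i) {
    accuracy_from_counts(as.list(studies[i, , drop = FALSE]), level)
  })
  class(out) <- c("nipt_accuracy", class(out))
  out
}

#' Pool validity studies by summing their 2x2 counts
#'
#' Element-wise sum of the counts followed by [accuracy_from_counts()] on
#' the pooled table; pooling is order-invariant, and the pooled sensitivity
#' and specificity are count-weighted means of the per-study values.
#'
#' @param studies Data frame with columns `tp`, `fn`, `tn`, `fp`.
#' @param level Confidence level.
#' @return List with `counts` (named totals) and `estimate` (one-row
#'   accuracy tibble labelled "Merged data").
#' @export
merge_studies <- function(studies, level = 0.95) {
  if (nrow(studies) == 0) abort("Cannot merge an empty study list.")
  counts <- list(study = "Merged data", approach = NA_character_,
                 tp = sum(studies$tp), fn = sum(studies$fn),
                 tn = sum(studies$tn), fp = sum(studies$fp))
  list(counts = c(tp = counts$tp, fn = counts$fn,
                  tn = counts$tn, fp = counts$fp),
       estimate = accuracy_from_counts(counts, level))
}

#' Packaged NIPT validity studies
#'
#' The eight published large-scale NIPT validity studies for Down's
#' syndrome, as true/false positive/negative counts, shipped as a CSV
#' fixture. The separately published pooled row (`pooled = TRUE`) does not
#' equal the column sums of the eight studies (736/5/11601/6 versus
#' 701/5/11480/6); both are provided as printed, and the discrepancy is
#' inherited from the source table rather than resolved here.
#'
#' @param pooled Return the published pooled row instead of the per-study
#'   rows.
#' @return A tibble with columns `study`, `approach`, `tp`, `fn`, `tn`, `fp`.
#' @export
nipt_validity_studies <- function(pooled = FALSE) {
  file <- if (pooled) "nipt_validity_pooled.csv" else "nipt_validity_studies.csv"
  path <- system.file("extdata", file, package = "niptscreen")
  tibble::as_tibble(read.csv(path, check.names = FALSE,
                             stringsAsFactors = FALSE))
}

#' Forest-style plot of per-study and pooled accuracy
#'
#' @param object A `nipt_accuracy` tibble (from [accuracy_table()]).
#' @param ... Unused.
#' @return A ggplot object showing sensitivity and specificity with score
#'   intervals per study.
#' @method autoplot nipt_accuracy
#' @export
autoplot.nipt_accuracy <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, study = .data$study, measure = "sensitivity",
                     point = .data$sensitivity, low = .data$sens_low,
                     high = .data$sens_high),
    dplyr::transmute(object, study = .data$study, measure = "specificity",
                     point = .data$specificity, low = .data$spec_low,
                     high = .data$spec_high)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$point, y = .data$study)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high), height = 0.2) +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "Per cent (95% score interval)", y = NULL) +
    ggplot2::theme_minimal()
}
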