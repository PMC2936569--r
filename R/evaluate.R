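check_metric_input <- function(truth, estimate, min_n = 3) {
  if (length(truth) != length(estimate)) stop("vectors must have equal length")
  if (length(truth) < min_n)
    stop(sprintf("at least %d observations are required", min_n))
  if (var(truth) == 0 || var(estimate) == 0)
    stop("metric undefined for a zero-variance vector")
  invisible(TRUE)
}

#' Prediction accuracy
#'
#' Sample Pearson correlation between true and predicted breeding values.
#'
#' @param tbv,gebv Numeric vectors of equal length (>= 3), each with
#'   positive variance.
#' @return Correlation in `[-1, 1]`.
#' @export
accuracy <- function(tbv, gebv) {
  check_metric_input(tbv, gebv)
  cor(tbv, gebv)
}

#' Rank correlation of predictions
#'
#' Spearman correlation (Pearson on average-tie ranks), the quantity that
#' matters under truncation selection.
#'
#' @inheritParams accuracy
#' @return Correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(tbv, gebv) {
  check_metric_input(tbv, gebv)
  cor(tbv, gebv, method = "spearman")
}

#' Bias of predictions
#'
#' Least-squares regression coefficient of TBV on GEBV; 1 means unbiased,
#' below 1 means the spread of the predictions overstates the true spread.
#'
#' @inheritParams accuracy
#' @return Regression slope.
#' @export
regression_bias <- function(tbv, gebv) {
  check_metric_input(tbv, gebv, min_n = 2)
  cov(tbv, gebv) / var(gebv)
}

#' Average per-generation decline in accuracy
#'
#' Persistency summary: the total drop from the first to the last
#' generation divided by the number of generation steps,
#' `(acc_first - acc_last) / (n - 1)`.
#'
#' @param accuracies Per-generation accuracies in generation order
#'   (length >= 2).
#' @return Mean one-generation decrease.
#' @export
#' @examples
#' decline_per_generation(c(0.8, 0.76, 0.72, 0.68, 0.64))   # 0.04
decline_per_generation <- function(accuracies) {
  if (length(accuracies) < 2) stop("at least two generations are required")
  (accuracies[1] - accuracies[length(accuracies)]) / (length(accuracies) - 1)
}

#' Evaluate predictions against true breeding values
#'
#' Joins predictions to truth by `id` and computes accuracy, rank
#' correlation and regression bias, grouped by any of `method` and
#' `generation` present in the inputs.
#'
#' @param predictions Tibble with `id`, `gebv` and optionally `method`.
#' @param truth Tibble with `id`, `tbv` and optionally `generation`.
#' @return Tibble of metrics, one row per group.
#' @export
evaluate_predictions <- function(predictions, truth) {
  dat <- inner_join(as_tibble(predictions), as_tibble(truth), by = "id")
  if (!"method" %in% names(dat) && !is.null(attr(predictions, "method")))
    dat$method <- attr(predictions, "method")
  keys <- intersect(c("method", "generation"), names(dat))
  dat |>
    group_by(across(all_of(keys))) |>
    summarise(n = dplyr::n(),
              accuracy = accuracy(.data$tbv, .data$gebv),
              rank_correlation = rank_correlation(.data$tbv, .data$gebv),
              bias = regression_bias(.data$tbv, .data$gebv),
              .groups = "drop")
}

#' Aggregate replicate results
#'
#' Means and standard errors (`sd / sqrt(n_replicates)`; `NA` for a single
#' replicate) of every metric, per method and generation.
#'
#' @param replicates Tibble of per-replicate metrics with columns
#'   `replicate`, `method`, `generation` and one column per metric.
#' @param metrics Metric columns to aggregate.
#' @return Long tibble: `method`, `generation`, `metric`, `mean`, `se`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(replicates,
                                 metrics = c("accuracy", "rank_correlation", "bias")) {
  replicates |>
    pivot_longer(all_of(metrics), names_to = "metric", values_to = "value") |>
    group_by(.data$method, .data$generation, .data$metric) |>
    summarise(mean = mean(.data$value),
              se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
              n_replicates = dplyr::n(), .groups = "drop")
}
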