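#' Reference per-class validation metrics
#'
#' A bundled table of reported per-class precision, recall, F1 and support
#' for the original chest-sensor deployment of this architecture: the
#' cascade's hold-out validation and a later real-time comparison of the
#' flat baseline against the cascade. It is used to check the F1 identity
#' `f1 = 2 * p * r / (p + r)` at the two-decimal precision the figures are
#' reported at. Three rows carry `rounding_artifact = TRUE`: there the
#' reported F1 differs by one unit in the second decimal from the value
#' recomputed from the reported (already rounded) precision and recall —
#' the expected behaviour when F1 was computed from unrounded inputs and
#' rounded independently.
#'
#' @return a tibble with columns `evaluation` (`"holdout"` or
#'   `"realtime"`), `model` (`"cascade"` or `"flat"`), `activity`,
#'   `precision`, `recall`, `f1`, `support`, `rounding_artifact`.
#' @examples
#' reference_validation_metrics()
#' @export
reference_validation_metrics <- function() {
  path <- system.file("extdata", "reference_validation_metrics.csv",
                      package = "harcascade", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Recompute F1 from reported precision/recall pairs
#'
#' Applies the harmonic-mean definition to each (precision, recall) pair of
#' a metrics table and rounds half-up to `digits` decimals, for consistency
#' checks against reported F1 values.
#'
#' @param table a data frame with `precision` and `recall` columns.
#' @param digits reporting precision (default 2).
#' @return the table with an added `f1_recomputed` column.
#' @export
recompute_f1 <- function(table, digits = 2) {
  stopifnot(all(c("precision", "recall") %in% names(table)))
  p <- table$precision
  r <- table$recall
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  mutate(as_tibble(table), f1_recomputed = round_half_up(f1, digits))
}
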