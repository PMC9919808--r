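#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects:
#' \itemize{
#'   \item `tidy(har_metrics)` — per-class precision/recall/F1/support;
#'     `glance()` — one row with overall accuracy and totals.
#'   \item `tidy(har_confusion)` — long counts with `true`, `predicted`,
#'     `n`.
#'   \item `tidy(har_cv)` — per-algorithm mean/std fold score; `glance()` —
#'     fold count, seed and the winning algorithm.
#'   \item `tidy(har_cascade)` / `tidy(har_flat)` — one row per fitted
#'     sub-model with its algorithm, seed and class set.
#' }
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name har-tidiers
NULL

#' @rdname har-tidiers
#' @export
tidy.har_metrics <- function(x, ...) x$per_class

#' @rdname har-tidiers
#' @export
glance.har_metrics <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, n = x$n,
         n_classes = nrow(x$per_class))
}

#' @rdname har-tidiers
#' @export
tidy.har_confusion <- function(x, ...) {
  m <- unclass(x)
  out <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(out) <- c("true", "predicted", "n")
  out$n <- as.integer(out$n)
  out
}

#' @rdname har-tidiers
#' @export
tidy.har_cv <- function(x, ...) x$summary

#' @rdname har-tidiers
#' @export
glance.har_cv <- function(x, ...) {
  tibble(k = x$k, seed = x$seed,
         n_algorithms = nrow(x$summary),
         best_algorithm = x$summary$algorithm[
           which.max(x$summary$mean_score)],
         best_mean_score = max(x$summary$mean_score))
}

#' @rdname har-tidiers
#' @export
tidy.har_cascade <- function(x, ...) {
  bind_rows(purrr::imap(x$models, function(m, nm) {
    tibble(model = nm, algorithm = m$spec$algorithm, seed = m$spec$seed,
           classes = paste(m$levels, collapse = ","))
  }))
}

#' @rdname har-tidiers
#' @export
tidy.har_flat <- function(x, ...) {
  tibble(model = "flat", algorithm = x$spec$algorithm, seed = x$spec$seed,
         classes = paste(x$model$levels, collapse = ","))
}
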