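#' Confusion matrix over a known class set
#'
#' `counts[i, j]` is the number of rows with true class `i` predicted as
#' class `j`. Per-class true positives are the diagonal; false positives are
#' the column sum minus the diagonal; false negatives the row sum minus the
#' diagonal.
#'
#' @param truth,estimate equal-length label vectors (character or factor).
#' @param levels class order; defaults to the union of levels observed, or
#'   the factor levels when `truth` is a factor.
#' @return an object of class `har_confusion` (an integer matrix with
#'   `true`/`predicted` dimnames).
#' @examples
#' confusion_matrix(c("sit", "sit", "fall"), c("sit", "fall", "fall"))
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length",
          class = "harcascade_invalid_input")
  }
  if (is.null(levels)) {
    levels <- if (is.factor(truth)) levels(truth) else
      sort(unique(c(as.character(truth), as.character(estimate))))
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  bad <- setdiff(unique(c(truth, estimate)), levels)
  if (length(bad) > 0) {
    abort(sprintf("label(s) outside the class set: %s",
                  paste(bad, collapse = ", ")),
          class = "harcascade_invalid_input")
  }
  m <- table(factor(truth, levels = levels),
             factor(estimate, levels = levels))
  m <- matrix(as.integer(m), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  structure(m, class = c("har_confusion", "matrix"))
}

#' @export
print.har_confusion <- function(x, ...) {
  cat("<har_confusion>\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1 their
#' harmonic mean `2 * P * R / (P + R)`. A metric whose denominator is zero
#' (a class never predicted, never present, or with `P + R = 0`) is defined
#' as 0 — the conservative convention.
#'
#' @param cm a [confusion_matrix()].
#' @param label optional single class; when omitted all classes are
#'   returned.
#' @return a tibble with columns `activity`, `precision`, `recall`, `f1`,
#'   `support`.
#' @examples
#' cm <- confusion_matrix(c("sit", "sit", "fall"), c("sit", "fall", "fall"))
#' precision_recall_f1(cm)
#' @export
precision_recall_f1 <- function(cm, label = NULL) {
  stopifnot(inherits(cm, "har_confusion"))
  m <- unclass(cm)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  out <- tibble(activity = rownames(m), precision = unname(p),
                recall = unname(r), f1 = unname(f1),
                support = unname(rowSums(m)))
  if (!is.null(label)) {
    if (!label %in% out$activity) {
      abort(sprintf("label %s not in the class set", label),
            class = "harcascade_invalid_input")
    }
    out <- out[out$activity == label, ]
  }
  out
}

#' Overall accuracy from a confusion matrix
#'
#' The fraction of correct predictions: trace over total count.
#'
#' @param cm a [confusion_matrix()].
#' @return a number in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "har_confusion"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) {
    abort("empty confusion matrix", class = "harcascade_invalid_input")
  }
  sum(diag(m)) / total
}

#' Full metrics report for a set of predictions
#'
#' @param truth,estimate equal-length label vectors.
#' @param levels optional class order.
#' @return an object of class `har_metrics`: per-class
#'   precision/recall/F1/support, overall accuracy and the confusion matrix.
#'   `tidy()` returns the per-class table, `glance()` a one-row summary.
#' @export
metrics_report <- function(truth, estimate, levels = NULL) {
  cm <- confusion_matrix(truth, estimate, levels)
  structure(list(per_class = precision_recall_f1(cm),
                 overall_accuracy = overall_accuracy(cm),
                 confusion = cm, n = sum(unclass(cm))),
            class = "har_metrics")
}

#' @export
print.har_metrics <- function(x, digits = 2, ...) {
  cat("<har_metrics>\n")
  tab <- x$per_class
  tab$precision <- round_half_up(tab$precision, digits)
  tab$recall <- round_half_up(tab$recall, digits)
  tab$f1 <- round_half_up(tab$f1, digits)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("Total support: %d   Overall accuracy: %s\n", x$n,
              format(round_half_up(x$overall_accuracy, digits),
                     nsmall = digits)))
  invisible(x)
}

# display rounding for reports: half-up at `digits` decimals, matching how
# the per-class tables are conventionally printed; internal values are
# never rounded
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# stratified index split: per leaf class, round(n_c * test_fraction) rows go
# to the test portion
stratified_split <- function(labels, test_fraction, seed) {
  labels <- as.character(labels)
  idx_by_class <- split(seq_along(labels), labels)
  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(purrr::map(idx_by_class, function(idx) {
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  train_idx <- setdiff(seq_along(labels), test_idx)
  for (cls in names(idx_by_class)) {
    if (!cls %in% labels[train_idx] || !cls %in% labels[test_idx]) {
      abort(sprintf("class %s absent from one side of the split", cls),
            class = "harcascade_stratification_error")
    }
  }
  list(train = sort(train_idx), test = sort(test_idx))
}

#' Hold-out evaluation with a stratified train/test split
#'
#' Splits the labelled feature table stratified by leaf activity (by default
#' 30% of each class held out for testing), fits either the cascade or the
#' flat baseline on the training portion and reports per-class
#' precision/recall/F1/support plus overall accuracy on the test portion.
#' Deterministic for a fixed seed, and invariant to row order of the input.
#'
#' @param features labelled feature table.
#' @param mode `"cascade"` or `"flat"`.
#' @param specs classifier spec(s), as in [train_cascade()] / [train_flat()].
#' @param test_fraction fraction held out, default 0.3.
#' @param seed integer seed for the split (the fit seeds live in the specs).
#' @param taxonomy the two-group taxonomy (cascade mode).
#' @return a `har_metrics` report with the fitted model attached as
#'   attribute `model`.
#' @examples
#' bench <- make_confusable_benchmark(sim_config(), 60, seed = 2)
#' rep <- evaluate_split(featurize_stream(bench), mode = "cascade", seed = 2)
#' glance(rep)
#' @export
evaluate_split <- function(features, mode = c("cascade", "flat"),
                           specs = classifier_spec("rf"),
                           test_fraction = 0.3, seed = 1L,
                           taxonomy = activity_taxonomy()) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)",
          class = "harcascade_invalid_config")
  }
  features <- arrange(as_tibble(features),
                      dplyr::across(dplyr::any_of("t")))
  split <- stratified_split(features$label, test_fraction, seed)
  train <- features[split$train, ]
  test <- features[split$test, ]
  model <- if (mode == "cascade") {
    train_cascade(train, specs, taxonomy)
  } else {
    train_flat(train, if (inherits(specs, "classifier_spec")) specs else
      specs[[1]])
  }
  preds <- predict(model, test)
  rep <- metrics_report(as_activity_factor(test$label), preds,
                        levels = activity_levels())
  attr(rep, "model") <- model
  rep
}
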