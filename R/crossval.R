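#' Paired stratified k-fold comparison of classification algorithms
#'
#' Evaluates a set of candidate algorithms on one labelled feature table
#' with stratified k-fold cross-validation (default 10 folds) and reports
#' the mean and standard deviation of fold accuracy per algorithm. The fold
#' assignment is drawn once and shared across every algorithm, so the
#' comparison is paired. The score is fold accuracy, in \[0, 1\]; higher is
#' better. Stratification keeps rare classes represented in every fold.
#'
#' @param features labelled feature table.
#' @param algorithms a named or unnamed list of [classifier_spec()]s, or a
#'   character vector of algorithm names. Defaults to the seven classical
#'   algorithms.
#' @param k number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed integer seed for the fold assignment.
#' @return an object of class `har_cv` with elements `summary` (tibble:
#'   `algorithm`, `mean_score`, `std_score`), `folds` (tibble of per-fold
#'   accuracies), `k`, `seed`. `tidy()` returns the summary.
#' @examples
#' bench <- make_confusable_benchmark(sim_config(), 60, seed = 4)
#' kfold_compare(featurize_stream(bench), algorithms = c("rf", "cart"),
#'               k = 3, seed = 4)
#' @export
kfold_compare <- function(features,
                          algorithms = c("rf", "knn", "cart", "svm", "lr",
                                         "lda", "nb"),
                          k = 10, seed = 1L) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if (!is.numeric(k) || k < 2) {
    abort("k must be at least 2", class = "harcascade_invalid_config")
  }
  k <- as.integer(k)
  if (is.character(algorithms)) {
    algorithms <- purrr::map(algorithms, classifier_spec, seed = seed)
  }
  stopifnot(all(vapply(algorithms, inherits, TRUE, "classifier_spec")))
  algo_names <- vapply(algorithms, function(s) s$algorithm, "")
  if (is.null(names(algorithms))) names(algorithms) <- algo_names

  labels <- as.character(features$label)
  class_n <- table(labels)
  if (any(class_n < k)) {
    abort(sprintf("class(es) with fewer than k members: %s",
                  paste(names(class_n)[class_n < k], collapse = ", ")),
          class = "harcascade_invalid_config")
  }
  fold_of <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cls in names(class_n)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })

  features <- as_tibble(features)
  folds <- purrr::imap(algorithms, function(spec, nm) {
    acc <- vapply(seq_len(k), function(f) {
      train <- features[fold_of != f, ]
      test <- features[fold_of == f, ]
      fit <- fit_classifier(spec, train[feature_names()], train$label)
      mean(as.character(predict_classifier(fit, test)) ==
             as.character(test$label))
    }, numeric(1))
    tibble(algorithm = nm, fold = seq_len(k), score = acc)
  })
  folds <- bind_rows(folds)
  summary <- folds |>
    group_by(.data$algorithm) |>
    summarise(mean_score = mean(.data$score),
              # population SD over the k fold scores
              std_score = sqrt(mean((.data$score - mean(.data$score))^2)),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_score))
  structure(list(summary = summary, folds = folds, k = k,
                 seed = as.integer(seed)),
            class = "har_cv")
}

#' @export
print.har_cv <- function(x, digits = 3, ...) {
  cat(sprintf("<har_cv> %d-fold stratified cross-validation (seed %d)\n",
              x$k, x$seed))
  tab <- x$summary
  tab$mean_score <- round_half_up(tab$mean_score, digits)
  tab$std_score <- round_half_up(tab$std_score, digits + 1)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}
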