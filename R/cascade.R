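#' Partition a labelled feature table into the three cascade datasets
#'
#' The cascade trains three models on taxonomically restricted views of the
#' same training data: the *binary* dataset is every row relabelled to its
#' normal/abnormal group; the *normal* dataset keeps only sit/walk/sleep
#' rows with their leaf labels; the *abnormal* dataset keeps only cough/fall
#' rows. The two leaf datasets partition the rows exactly, so
#' `nrow(binary) == nrow(normal) + nrow(abnormal)`.
#'
#' @param features a feature table with a `label` column of leaf activities.
#' @param taxonomy the two-group taxonomy, by default [activity_taxonomy()].
#' @return a named list of tibbles: `binary`, `normal`, `abnormal`.
#' @examples
#' bench <- make_confusable_benchmark(sim_config(), 50, seed = 1)
#' d <- build_cascade_datasets(featurize_stream(bench))
#' sapply(d, nrow)
#' @export
build_cascade_datasets <- function(features, taxonomy = activity_taxonomy()) {
  stopifnot(is.data.frame(features))
  if (!"label" %in% names(features)) {
    abort("features must carry a label column",
          class = "harcascade_invalid_input")
  }
  labels <- as.character(features$label)
  check_activity_labels(labels, allowed = taxonomy$activity)
  groups <- activity_group(labels, taxonomy)
  binary <- as_tibble(features)
  binary$label <- groups
  list(
    binary = binary,
    normal = as_tibble(features)[groups == "normal", , drop = FALSE],
    abnormal = as_tibble(features)[groups == "abnormal", , drop = FALSE]
  )
}

resolve_specs <- function(specs) {
  if (inherits(specs, "classifier_spec")) {
    specs <- list(binary = specs, normal = specs, abnormal = specs)
  }
  stopifnot(is.list(specs),
            all(c("binary", "normal", "abnormal") %in% names(specs)))
  specs[c("binary", "normal", "abnormal")]
}

#' Train the hierarchical classifier cascade
#'
#' Fits three classifiers on the datasets of [build_cascade_datasets()]: a
#' binary normal-vs-abnormal router on all rows, a three-class model on the
#' normal rows only and a two-class model on the abnormal rows only. Task
#' division lets each model focus on fewer, more specific categories than a
#' single five-class model. The three fits share no state — they are
#' logically independent (and could be fitted in parallel); here they are
#' fitted sequentially, each under its own seed.
#'
#' @param features labelled feature table (nine feature columns + `label`).
#' @param specs either one [classifier_spec()] used for all three models, or
#'   a named list with elements `binary`, `normal`, `abnormal` — the cascade
#'   may mix algorithms. Default: random forest with 100 trees everywhere.
#' @param taxonomy the two-group taxonomy.
#' @return an object of class `har_cascade` holding the three fitted models,
#'   the taxonomy, the specs and the feature order.
#' @examples
#' bench <- make_confusable_benchmark(sim_config(), 60, seed = 5)
#' fit <- train_cascade(featurize_stream(bench))
#' fit
#' @export
train_cascade <- function(features, specs = classifier_spec("rf"),
                          taxonomy = activity_taxonomy()) {
  specs <- resolve_specs(specs)
  d <- build_cascade_datasets(features, taxonomy)
  for (nm in names(d)) {
    if (nrow(d[[nm]]) == 0 || length(unique(d[[nm]]$label)) < 2) {
      abort(sprintf("the %s sub-dataset is untrainable (needs >= 2 classes)",
                    nm),
            class = "harcascade_untrainable")
    }
  }
  models <- purrr::imap(d, function(dat, nm) {
    fit_classifier(specs[[nm]], dat[feature_names()], dat$label)
  })
  structure(list(models = models, taxonomy = taxonomy, specs = specs,
                 features = feature_names()),
            class = "har_cascade")
}

#' @export
print.har_cascade <- function(x, ...) {
  cat("<har_cascade> three-model hierarchical classifier\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-8s %-4s -> {%s}\n", nm, m$spec$algorithm,
                paste(m$levels, collapse = ", ")))
  }
  invisible(x)
}

#' Predict leaf activities with the cascade's logical execution
#'
#' For every row the binary model decides normal vs abnormal; abnormal rows
#' are passed to the cough/fall model, normal rows to the sit/walk/sleep
#' model. The output is always a leaf activity, and it lies in
#' `{cough, fall}` exactly when the router said abnormal.
#'
#' @param object a `har_cascade`.
#' @param newdata a feature table with the nine feature columns.
#' @param ... unused.
#' @return a factor of leaf activity labels, one per row of `newdata`.
#' @export
predict.har_cascade <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  route <- predict_classifier(object$models$binary, newdata)
  out <- character(nrow(newdata))
  abn <- route == "abnormal"
  if (any(abn)) {
    out[abn] <- as.character(
      predict_classifier(object$models$abnormal, newdata[abn, , drop = FALSE]))
  }
  if (any(!abn)) {
    out[!abn] <- as.character(
      predict_classifier(object$models$normal, newdata[!abn, , drop = FALSE]))
  }
  as_activity_factor(out)
}

#' Train the flat five-class baseline model
#'
#' The conventional approach: one classifier trained on all five leaf
#' activities at once. Used as the comparison baseline for the cascade.
#'
#' @param features labelled feature table.
#' @param spec a [classifier_spec()]; defaults to the same random-forest
#'   configuration as the cascade models.
#' @return an object of class `har_flat`.
#' @export
train_flat <- function(features, spec = classifier_spec("rf")) {
  stopifnot(is.data.frame(features))
  if (!"label" %in% names(features)) {
    abort("features must carry a label column",
          class = "harcascade_invalid_input")
  }
  check_activity_labels(features$label)
  if (length(unique(features$label)) < 2) {
    abort("flat model is untrainable on a single class",
          class = "harcascade_untrainable")
  }
  model <- fit_classifier(spec, features[feature_names()], features$label)
  structure(list(model = model, spec = spec, features = feature_names()),
            class = "har_flat")
}

#' @export
print.har_flat <- function(x, ...) {
  cat(sprintf("<har_flat> %s five-class model -> {%s}\n",
              x$spec$algorithm, paste(x$model$levels, collapse = ", ")))
  invisible(x)
}

#' @rdname train_flat
#' @param object a `har_flat`.
#' @param newdata feature table.
#' @param ... unused.
#' @export
predict.har_flat <- function(object, newdata, ...) {
  as_activity_factor(as.character(
    predict_classifier(object$model, as.data.frame(newdata))))
}
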