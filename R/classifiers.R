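#' Specify a classification algorithm
#'
#' One spec per fitted model. Seven classical algorithms are supported —
#' random forest (`rf`), k-nearest neighbours (`knn`), a classification tree
#' (`cart`), a support vector machine (`svm`), multinomial logistic
#' regression (`lr`), linear discriminant analysis (`lda`) and Gaussian
#' naive Bayes (`nb`) — plus a constant `majority` baseline that always
#' predicts the modal training class (useful as a floor in algorithm
#' comparisons). The random-forest default mirrors the deployed
#' configuration: 100 trees, a minimum of 1 sample per leaf and 2 samples to
#' split a node.
#'
#' @param algorithm one of `"rf"`, `"knn"`, `"cart"`, `"svm"`, `"lr"`,
#'   `"lda"`, `"nb"`, `"majority"`.
#' @param ... algorithm-specific hyperparameters passed to the underlying
#'   fit function (`randomForest::randomForest`, `class::knn` (`k`, default
#'   5), `rpart::rpart`, `e1071::svm`, `nnet::multinom`, `MASS::lda`,
#'   `e1071::naiveBayes`).
#' @param seed integer seed threaded through every stochastic fit and
#'   prediction for reproducibility.
#' @return an object of class `classifier_spec`.
#' @examples
#' classifier_spec("rf", seed = 42)
#' classifier_spec("knn", k = 3)
#' @export
classifier_spec <- function(algorithm = c("rf", "knn", "cart", "svm", "lr",
                                          "lda", "nb", "majority"),
                            ..., seed = 1L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, hyper = list(...),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyper)) {
    paste0(" (", paste(names(x$hyper), unlist(x$hyper), sep = "=",
                       collapse = ", "), ")")
  } else ""
  cat(sprintf("<classifier_spec> %s%s, seed %d\n", x$algorithm, hp, x$seed))
  invisible(x)
}

fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.data.frame(x)[feature_names()]
  y <- droplevels(factor(y))
  if (nlevels(y) < 2 && spec$algorithm != "majority") {
    abort(sprintf("cannot train a %s model on a single class (%s)",
                  spec$algorithm, levels(y)),
          class = "harcascade_untrainable")
  }
  hp <- spec$hyper
  fit <- withr::with_seed(spec$seed, switch(spec$algorithm,
    rf = do.call(randomForest::randomForest,
                 c(list(x = x, y = y),
                   utils::modifyList(list(ntree = 100, nodesize = 1), hp))),
    knn = list(train = as.matrix(x), cl = y, k = hp$k %||% 5L),
    cart = rpart::rpart(label ~ ., data = cbind(x, label = y),
                        method = "class"),
    svm = do.call(e1071::svm, c(list(x = as.matrix(x), y = y), hp)),
    lr = do.call(nnet::multinom,
                 c(list(label ~ ., data = cbind(x, label = y),
                        trace = FALSE, maxit = 200), hp)),
    lda = do.call(MASS::lda, c(list(x = x, grouping = y), hp)),
    nb = do.call(e1071::naiveBayes,
                 c(list(label ~ ., data = cbind(x, label = y)), hp)),
    majority = names(sort(table(y), decreasing = TRUE))[1]
  ))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = feature_names()),
            class = "har_classifier")
}

predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "har_classifier"))
  x <- as.data.frame(x)
  missing <- setdiff(model$features, names(x))
  if (length(missing) > 0) {
    abort(sprintf("feature column(s) missing: %s",
                  paste(missing, collapse = ", ")),
          class = "harcascade_invalid_input")
  }
  x <- x[model$features]
  spec <- model$spec
  out <- withr::with_seed(spec$seed, switch(spec$algorithm,
    rf = predict(model$fit, x),
    knn = class::knn(model$fit$train, as.matrix(x), model$fit$cl,
                     k = model$fit$k),
    cart = predict(model$fit, x, type = "class"),
    svm = predict(model$fit, as.matrix(x)),
    lr = predict(model$fit, x, type = "class"),
    lda = predict(model$fit, x)$class,
    nb = predict(model$fit, x),
    majority = factor(rep(model$fit, nrow(x)), levels = model$levels)
  ))
  factor(as.character(out), levels = model$levels)
}
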