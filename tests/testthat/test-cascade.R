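test_that("cascade datasets partition the training rows exactly", {
  df <- make_blobs(10)[1:15, ]
  df$label <- c(rep("sit", 10), rep("cough", 5))
  d <- build_cascade_datasets(df)
  expect_equal(nrow(d$binary), 15)
  expect_equal(sum(d$binary$label == "normal"), 10)
  expect_equal(sum(d$binary$label == "abnormal"), 5)
  expect_equal(nrow(d$normal), 10)
  expect_equal(nrow(d$abnormal), 5)
  # conservation: leaf multiset of the two sub-datasets equals the input
  expect_equal(sort(c(d$normal$label, d$abnormal$label)), sort(df$label))
  expect_equal(nrow(d$binary), nrow(d$normal) + nrow(d$abnormal))
})

test_that("degenerate partitions are flagged as untrainable", {
  df <- make_blobs(10)
  normal_only <- df[df$label %in% c("sit", "walk", "sleep"), ]
  d <- build_cascade_datasets(normal_only)
  expect_equal(nrow(d$abnormal), 0)
  expect_error(train_cascade(normal_only), class = "harcascade_untrainable")
  # a single abnormal class is reported by the model that cannot be fitted
  one_abnormal <- df[df$label %in% c("sit", "walk", "cough"), ]
  expect_error(train_cascade(one_abnormal), "abnormal",
               class = "harcascade_untrainable")
  bad <- df
  bad$label[1] <- "jump"
  expect_error(build_cascade_datasets(bad), class = "harcascade_invalid_label")
})

test_that("cascade and flat models fit separable data perfectly and deterministically", {
  df <- make_blobs(30)
  casc <- train_cascade(df, classifier_spec("rf", seed = 42))
  # each sub-model reproduces its own training rows
  d <- build_cascade_datasets(df)
  for (nm in names(d)) {
    sub <- harcascade:::predict_classifier(casc$models[[nm]], d[[nm]])
    expect_equal(mean(as.character(sub) == d[[nm]]$label), 1)
  }
  flat <- train_flat(df, classifier_spec("rf", seed = 42))
  expect_equal(mean(as.character(predict(flat, df)) == df$label), 1)
  expect_equal(mean(as.character(predict(casc, df)) == df$label), 1)

  probe <- make_blobs(10, seed = 123)
  casc2 <- train_cascade(df, classifier_spec("rf", seed = 42))
  expect_identical(predict(casc, probe), predict(casc2, probe))

  # the deployed default: 100-tree random forest in every position
  expect_equal(casc$models$binary$fit$ntree, 100)
  expect_equal(flat$model$fit$ntree, 100)
})

test_that("logical execution matches a row-by-row two-stage oracle", {
  df <- make_blobs(30)
  casc <- train_cascade(df, classifier_spec("rf", seed = 1))
  probe <- make_blobs(20, sd = 1.5, seed = 7)   # blurred rows, both routes
  fast <- as.character(predict(casc, probe))
  slow <- vapply(seq_len(nrow(probe)), function(i) {
    row <- probe[i, , drop = FALSE]
    route <- as.character(
      harcascade:::predict_classifier(casc$models$binary, row))
    sub <- if (route == "abnormal") casc$models$abnormal else
      casc$models$normal
    as.character(harcascade:::predict_classifier(sub, row))
  }, "")
  expect_identical(fast, slow)
})

test_that("routing is sound: abnormal route iff output is cough or fall", {
  df <- make_blobs(30)
  casc <- train_cascade(df, classifier_spec("rf", seed = 1))
  probe <- make_blobs(40, sd = 2, seed = 5)
  out <- as.character(predict(casc, probe))
  route <- as.character(
    harcascade:::predict_classifier(casc$models$binary, probe))
  expect_identical(out %in% c("cough", "fall"), route == "abnormal")
  expect_true(all(out %in% activity_levels()))
})

test_that("the posture model never influences rows routed abnormal", {
  df <- make_blobs(30)
  casc <- train_cascade(df, classifier_spec("rf", seed = 1))
  probe <- make_blobs(40, sd = 2, seed = 9)
  route <- as.character(
    harcascade:::predict_classifier(casc$models$binary, probe))
  before <- as.character(predict(casc, probe))
  # replace the sit/walk/sleep model with a constant predictor
  mangled <- casc
  mangled$models$normal <- harcascade:::fit_classifier(
    classifier_spec("majority"),
    df[df$label == "walk", feature_names()],
    df$label[df$label == "walk"])
  after <- as.character(predict(mangled, probe))
  expect_identical(before[route == "abnormal"], after[route == "abnormal"])
})

test_that("flat predictions are leaf labels, one per row", {
  df <- make_blobs(20)
  flat <- train_flat(df, classifier_spec("cart", seed = 2))
  probe <- make_blobs(15, sd = 1, seed = 3)
  out <- predict(flat, probe)
  expect_length(out, nrow(probe))
  expect_true(all(as.character(out) %in% activity_levels()))
  one_class <- df[df$label == "sit", ]
  expect_error(train_flat(one_class), class = "harcascade_untrainable")
})

test_that("every supported algorithm can drive the cascade", {
  df <- make_blobs(20)
  probe <- make_blobs(5, seed = 31)
  for (algo in c("knn", "cart", "nb", "lda")) {
    casc <- train_cascade(df, classifier_spec(algo, seed = 3))
    expect_true(all(as.character(predict(casc, probe)) %in%
                      activity_levels()))
  }
})

test_that("a saved model directory restores to identical predictions", {
  df <- make_blobs(20)
  probe <- make_blobs(10, sd = 1, seed = 17)
  dir <- withr::local_tempdir()

  casc <- train_cascade(df, classifier_spec("rf", seed = 6))
  save_model(casc, file.path(dir, "cascade"))
  expect_true(file.exists(file.path(dir, "cascade", "manifest.yaml")))
  restored <- load_model(file.path(dir, "cascade"))
  expect_identical(predict(restored, probe), predict(casc, probe))
  expect_equal(restored$taxonomy, casc$taxonomy)

  flat <- train_flat(df, classifier_spec("cart", seed = 6))
  save_model(flat, file.path(dir, "flat"))
  restored_flat <- load_model(file.path(dir, "flat"))
  expect_identical(predict(restored_flat, probe), predict(flat, probe))
})
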