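test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c("sit", "sit", "fall"), c("sit", "fall", "fall"))
  expect_equal(cm["sit", "sit"], 1)
  expect_equal(cm["sit", "fall"], 1)
  expect_equal(cm["fall", "fall"], 1)
  expect_equal(sum(cm), 3)
  expect_equal(overall_accuracy(cm), 2 / 3)

  perfect <- confusion_matrix(activity_levels(), activity_levels())
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(overall_accuracy(perfect), 1)

  wrong <- confusion_matrix(c("sit", "walk"), c("walk", "sit"))
  expect_equal(overall_accuracy(wrong), 0)

  expect_error(confusion_matrix("sit", c("sit", "sit")),
               class = "harcascade_invalid_input")
})

test_that("precision, recall and F1 follow their definitions", {
  # TP=2, FP=1, FN=3 for class a: P=2/3, R=2/5, F1=1/2
  truth <- c(rep("a", 5), rep("b", 4))
  pred <- c("a", "a", "b", "b", "b", "a", "b", "b", "b")
  cm <- confusion_matrix(truth, pred)
  m <- precision_recall_f1(cm, "a")
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 5)
  expect_equal(m$f1, 1 / 2)
  expect_equal(m$support, 5)

  # perfect classifier
  cmp <- confusion_matrix(truth, truth)
  mp <- precision_recall_f1(cmp)
  expect_true(all(mp$precision == 1 & mp$recall == 1 & mp$f1 == 1))

  # a class never predicted and never present gets 0, not NaN
  cm0 <- confusion_matrix(c("a", "a"), c("a", "a"), levels = c("a", "b"))
  m0 <- precision_recall_f1(cm0, "b")
  expect_equal(unlist(m0[c("precision", "recall", "f1")]),
               c(0, 0, 0), ignore_attr = TRUE)
})

test_that("reported-style rounding reproduces F1 from precision/recall pairs", {
  tab <- recompute_f1(data.frame(precision = 0.88, recall = 1.00))
  expect_equal(tab$f1_recomputed, 0.94)
  expect_equal(recompute_f1(data.frame(precision = 1, recall = 1))$f1_recomputed, 1)
  expect_equal(recompute_f1(data.frame(precision = 0, recall = 0))$f1_recomputed, 0)
})

test_that("micro-averaged precision and recall equal overall accuracy", {
  withr::with_seed(8, {
    for (i in 1:25) {
      k <- sample(2:5, 1)
      lv <- letters[1:k]
      n <- sample(20:80, 1)
      truth <- sample(lv, n, replace = TRUE)
      pred <- sample(lv, n, replace = TRUE)
      cm <- confusion_matrix(truth, pred, levels = lv)
      m <- unclass(cm)
      tp <- sum(diag(m))
      micro_p <- tp / sum(colSums(m))
      micro_r <- tp / sum(rowSums(m))
      expect_equal(micro_p, overall_accuracy(cm))
      expect_equal(micro_r, overall_accuracy(cm))
    }
  })
})

test_that("metric path agrees with the brute-force pair counter", {
  withr::with_seed(17, {
    for (i in 1:50) {
      lv <- activity_levels()
      n <- sample(10:60, 1)
      truth <- sample(lv, n, replace = TRUE)
      pred <- sample(lv, n, replace = TRUE)
      per <- precision_recall_f1(confusion_matrix(truth, pred, levels = lv))
      for (label in lv) {
        o <- oracle_prf(truth, pred, label)
        row <- per[per$activity == label, ]
        expect_equal(row$precision, unname(o["precision"]))
        expect_equal(row$recall, unname(o["recall"]))
        expect_equal(row$f1, unname(o["f1"]))
      }
    }
  })
})

test_that("the hold-out split is stratified with the expected sizes", {
  df <- make_blobs(200)   # 1000 rows, 200 per class
  rep <- evaluate_split(df, mode = "flat",
                        specs = classifier_spec("cart", seed = 4),
                        test_fraction = 0.3, seed = 4)
  expect_s3_class(rep, "har_metrics")
  expect_equal(rep$n, 300)
  expect_equal(unname(rep$per_class$support), rep(60, 5))
  expect_named(tidy(rep), c("activity", "precision", "recall", "f1",
                            "support"))
  expect_equal(glance(rep)$overall_accuracy, 1)
})

test_that("hold-out evaluation is invariant to row shuffling", {
  df <- make_blobs(40)
  shuffled <- withr::with_seed(2, df[sample(nrow(df)), ])
  a <- evaluate_split(df, "flat", classifier_spec("cart", seed = 9), seed = 9)
  b <- evaluate_split(shuffled, "flat", classifier_spec("cart", seed = 9),
                      seed = 9)
  expect_equal(unclass(a$confusion), unclass(b$confusion))
})

test_that("stratification failures and bad fractions are reported", {
  df <- make_blobs(40)
  rare <- df[c(which(df$label != "fall"), which(df$label == "fall")[1]), ]
  expect_error(evaluate_split(rare, "flat", seed = 1),
               class = "harcascade_stratification_error")
  expect_error(evaluate_split(df, "flat", test_fraction = 0),
               class = "harcascade_invalid_config")
})
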