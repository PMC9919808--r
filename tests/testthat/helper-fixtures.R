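# shared fixtures, all generated in code

# noiseless acquisition config for exact-value tests
quiet_cfg <- function(seed = 1L, ...) {
  sim_config(noise_sd_g = 0, spike_prob = 0, seed = seed, ...)
}

# five well-separated Gaussian blobs in the 9-feature space, one per
# activity; trivially separable by construction
make_blobs <- function(n_per_class = 50, sd = 0.02, seed = 99) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(5 * 9, sd = 4), nrow = 5)
    out <- lapply(1:5, function(c) {
      m <- matrix(rnorm(n_per_class * 9, sd = sd), ncol = 9) +
        matrix(centers[c, ], n_per_class, 9, byrow = TRUE)
      df <- as.data.frame(m)
      names(df) <- feature_names()
      df$label <- activity_levels()[c]
      df
    })
    df <- do.call(rbind, out)
    df$t <- seq_len(nrow(df)) / 10
    tibble::as_tibble(df)
  })
}

# brute-force per-class precision/recall/F1 by explicit pair counting,
# independent of the confusion-matrix path
oracle_prf <- function(truth, pred, label) {
  tp <- sum(truth == label & pred == label)
  fp <- sum(truth != label & pred == label)
  fn <- sum(truth == label & pred != label)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

# a stream whose featurized rows, labelled as `labels`, train a 1-NN flat
# model that reproduces exactly that label sequence on replay: lets tests
# script arbitrary prediction sequences through the event machinery
scripted_predictor <- function(stream, labels) {
  feats <- featurize_stream(stream)
  feats$label <- labels
  train_flat(feats, classifier_spec("knn", k = 1, seed = 1))
}

# raw sample sequence with enough variety that consecutive rows differ
scripted_stream <- function(labels, t0 = 0) {
  n <- length(labels)
  withr::with_seed(42, tibble::tibble(
    t = t0 + seq_len(n) / 10,
    x = round(runif(n, -1, 1), 3),
    y = round(runif(n, -1, 1), 3),
    z = round(runif(n, -1, 1), 3)
  ))
}
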