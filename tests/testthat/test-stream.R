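# the scripted 1-NN predictor reproduces an arbitrary label sequence on
# replay, so event semantics can be tested against exact prediction scripts

test_that("a fall latches across later normal predictions", {
  labels <- c("fall", "sit", "sit")
  st <- scripted_stream(labels)
  model <- scripted_predictor(st, labels)
  log <- replay(st, model)
  expect_equal(log$prediction, labels)
  expect_equal(log$fall, c(1L, 1L, 1L))
  expect_equal(log$sit, c(0L, 1L, 1L))
  s <- attr(log, "summary")
  expect_true(s$fall_latched)
  expect_equal(s$first_fall_t, st$t[1])
})

test_that("streams without risk events leave the state quiet", {
  labels <- rep(c("sit", "walk", "sleep"), each = 4)
  st <- scripted_stream(labels)
  log <- replay(st, scripted_predictor(st, labels))
  s <- attr(log, "summary")
  expect_equal(s$cough_episodes, 0L)
  expect_false(s$fall_latched)
  expect_true(all(log$fall == 0 & log$cough == 0))
})

test_that("cough episodes are counted by run, not by sample", {
  labels <- c("cough", "cough", "sit", "cough")
  st <- scripted_stream(labels)
  log <- replay(st, scripted_predictor(st, labels))
  expect_equal(attr(log, "summary")$cough_episodes, 2L)
})

test_that("the daily cough count resets at a day boundary", {
  labels <- c("cough", "sit", "cough", "sit", "cough", "sit")
  # last two samples fall on the next calendar day of stream time
  st <- scripted_stream(labels)
  st$t <- c(86395, 86396, 86397, 86398, 86401, 86402)
  model <- scripted_predictor(st, labels)
  state <- event_state()
  prev <- NULL
  counts <- integer(0)
  for (i in seq_len(nrow(st))) {
    out <- stream_step(state, st[i, ], model, prev)
    state <- out$state
    prev <- st[i, ]
    counts <- c(counts, state$cough_count_today)
  }
  expect_equal(counts, c(1L, 1L, 2L, 2L, 1L, 1L))
})

test_that("fall reset clears the latch, is idempotent, and re-latches", {
  labels <- c("fall", "sit", "fall")
  st <- scripted_stream(labels)
  model <- scripted_predictor(st, labels)
  state <- event_state()
  out1 <- stream_step(state, st[1, ], model, NULL)
  expect_true(out1$state$fall_latched)
  cleared <- reset_fall(out1$state)
  expect_false(cleared$fall_latched)
  expect_identical(reset_fall(cleared)$fall_latched, FALSE)
  expect_equal(cleared$current_activity, out1$state$current_activity)
  out2 <- stream_step(cleared, st[2, ], model, st[1, ])
  expect_false(out2$state$fall_latched)
  out3 <- stream_step(out2$state, st[3, ], model, st[2, ])
  expect_true(out3$state$fall_latched)
})

test_that("stream_step and batch replay agree sample for sample", {
  labels <- c("sit", "cough", "cough", "walk", "fall", "sleep")
  st <- scripted_stream(labels)
  model <- scripted_predictor(st, labels)
  log <- replay(st, model)
  state <- event_state()
  prev <- NULL
  for (i in seq_len(nrow(st))) {
    out <- stream_step(state, st[i, ], model, prev)
    state <- out$state
    prev <- st[i, ]
    expect_equal(out$message, log[i, names(out$message)],
                 ignore_attr = TRUE)
  }
  expect_equal(state$cough_count_today,
               attr(log, "summary")$cough_episodes)
})

test_that("every message asserts exactly one current activity", {
  labels <- c("sit", "fall", "walk", "cough", "sleep", "sit")
  st <- scripted_stream(labels)
  log <- replay(st, scripted_predictor(st, labels))
  ind <- as.matrix(log[activity_levels()])
  extra <- as.integer(log$fall == 1 & log$prediction != "fall")
  expect_equal(rowSums(ind) - extra, rep(1, nrow(log)))
  # latch monotonicity: after its first 1 the fall channel never drops
  first1 <- match(1L, log$fall)
  expect_true(all(log$fall[first1:nrow(log)] == 1))
})

test_that("replay handles files, empty input, and writes a JSONL log", {
  labels <- c("sit", "cough", "sit")
  st <- scripted_stream(labels)
  model <- scripted_predictor(st, labels)
  dir <- withr::local_tempdir()

  csv <- file.path(dir, "stream.csv")
  write_accel(st, csv)
  out <- file.path(dir, "events.jsonl")
  log <- replay(csv, model, out = out)
  expect_equal(nrow(log), nrow(st))
  lines <- readLines(out)
  expect_length(lines, nrow(st) + 1)   # messages plus summary line
  msg <- jsonlite::fromJSON(lines[1])
  expect_named(msg, c("t", "cough", "fall", "sit", "walk", "sleep"))
  expect_true(jsonlite::fromJSON(lines[length(lines)])$summary)

  empty <- replay(st[0, ], model)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "summary")$cough_episodes, 0L)
  expect_false(attr(empty, "summary")$fall_latched)

  log2 <- replay(csv, model)
  expect_equal(log2$prediction, log$prediction)
  expect_error(stream_step(event_state(), st[1, ], "not a model"),
               class = "harcascade_invalid_state")
})
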