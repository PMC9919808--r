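#' Streaming event state
#'
#' Tracks the risk-event semantics of the live system: once a fall is
#' predicted the fall indicator *latches* and stays asserted — independent
#' of later predictions — until [reset_fall()] models the wearer (or a
#' caregiver) pressing the restart button. Coughs are counted per day as
#' *episodes*: a maximal run of consecutive cough predictions counts once,
#' since counting every 10 Hz sample would inflate the tally roughly
#' tenfold per second of coughing. The day boundary uses the sample
#' timestamp (seconds, day key `floor(t / 86400)`), not the wall clock.
#'
#' @return `event_state()` returns a fresh `har_event_state`;
#'   `reset_fall()` returns the state with the fall latch cleared
#'   (idempotent), all other fields untouched.
#' @export
event_state <- function() {
  structure(list(fall_latched = FALSE, cough_count_today = 0L,
                 current_activity = NA_character_, day_key = NA_real_,
                 prev_prediction = NA_character_),
            class = "har_event_state")
}

#' @rdname event_state
#' @param state a `har_event_state`.
#' @export
reset_fall <- function(state) {
  stopifnot(inherits(state, "har_event_state"))
  state$fall_latched <- FALSE
  state
}

#' @export
print.har_event_state <- function(x, ...) {
  cat(sprintf(
    "<har_event_state> activity=%s fall_latched=%s coughs_today=%d\n",
    x$current_activity %||% NA, x$fall_latched, x$cough_count_today))
  invisible(x)
}

activity_message <- function(t, activity, fall_latched) {
  msg <- setNames(as.list(as.integer(activity_levels() == activity)),
                  activity_levels())
  if (fall_latched) msg$fall <- 1L
  as_tibble(c(list(t = t), msg))
}

#' Advance the streaming recogniser by one sample
#'
#' Featurizes the incoming sample against the previous one (all delta
#' features are 0 at stream start), predicts the activity through the
#' cascade, updates the event state (fall latching, daily cough-episode
#' count, day rollover) and emits one activity message: a row of 0/1
#' indicators `{t, cough, fall, sit, walk, sleep}` matching a dashboard
#' contract where 1 lights the activity's box. Exactly one indicator
#' reflects the current prediction; the fall channel may additionally stay
#' at 1 while latched.
#'
#' @param state a [event_state()].
#' @param sample a one-row data frame (or named list) with `t`, `x`, `y`,
#'   `z`.
#' @param cascade a trained [train_cascade()] model (a flat model works
#'   too).
#' @param prev_sample the immediately preceding sample, or `NULL` at stream
#'   start.
#' @return a list with elements `state` (updated) and `message` (one-row
#'   tibble).
#' @export
stream_step <- function(state, sample, cascade, prev_sample = NULL) {
  stopifnot(inherits(state, "har_event_state"))
  if (!inherits(cascade, c("har_cascade", "har_flat"))) {
    abort("cascade must be a trained model",
          class = "harcascade_invalid_state")
  }
  sample <- as.list(sample)
  feats <- featurize_pair(sample, prev_sample)
  pred <- as.character(predict(cascade, feats))

  day <- floor(sample$t / 86400)
  if (!is.na(state$day_key) && day != state$day_key) {
    state$cough_count_today <- 0L
  }
  state$day_key <- day
  if (pred == "fall") state$fall_latched <- TRUE
  if (pred == "cough" &&
      (is.na(state$prev_prediction) || state$prev_prediction != "cough")) {
    state$cough_count_today <- state$cough_count_today + 1L
  }
  state$prev_prediction <- pred
  state$current_activity <- pred
  list(state = state,
       message = activity_message(sample$t, pred, state$fall_latched))
}

#' Replay a recorded stream through the recogniser
#'
#' Runs [stream_step()] over every sample of a stream (a tibble or a
#' CSV/JSONL file readable by [read_accel()]) in order and returns the full
#' event log: one message per sample plus the per-sample prediction (and
#' the true label when the stream is labelled). The episode/latch summary
#' is attached as attribute `summary`. When `out` is given the messages are
#' also written as JSON Lines and the summary as a final summary object.
#'
#' @param stream a data frame with `t`, `x`, `y`, `z` (optional `label`) or
#'   a file path.
#' @param cascade a trained cascade (or flat) model.
#' @param out optional path for a JSONL event log.
#' @return a tibble with columns `t`, the five indicator columns,
#'   `prediction` and (if available) `label`; attribute `summary` is a list
#'   with `cough_episodes`, `fall_latched`, `first_fall_t`, `n_samples`.
#' @examples
#' s <- simulate_scenario(list(activity_segment("sit", 5),
#'                             activity_segment("walk", 5)),
#'                        sim_config(seed = 11))
#' fit <- train_cascade(featurize_stream(
#'   make_confusable_benchmark(sim_config(), 60, seed = 11)))
#' log <- replay(s, fit)
#' attr(log, "summary")
#' @export
replay <- function(stream, cascade, out = NULL) {
  if (is.character(stream)) stream <- read_accel(stream)
  stopifnot(is.data.frame(stream))
  n <- nrow(stream)
  if (n == 0) {
    log <- tibble(t = double(), cough = integer(), fall = integer(),
                  sit = integer(), walk = integer(), sleep = integer(),
                  prediction = character())
    attr(log, "summary") <- list(cough_episodes = 0L, fall_latched = FALSE,
                                 first_fall_t = NA_real_, n_samples = 0L)
    if (!is.null(out)) writeLines(character(0), out)
    return(log)
  }
  # batch-featurize once (identical to per-sample featurization against the
  # previous sample), then walk the event state through the predictions
  feats <- featurize_stream(stream)
  preds <- as.character(predict(cascade, feats))
  state <- event_state()
  msgs <- vector("list", n)
  first_fall_t <- NA_real_
  for (i in seq_len(n)) {
    t_i <- stream$t[i]
    day <- floor(t_i / 86400)
    if (!is.na(state$day_key) && day != state$day_key) {
      state$cough_count_today <- 0L
    }
    state$day_key <- day
    pred <- preds[i]
    if (pred == "fall") {
      if (!state$fall_latched) first_fall_t <- t_i
      state$fall_latched <- TRUE
    }
    if (pred == "cough" &&
        (is.na(state$prev_prediction) || state$prev_prediction != "cough")) {
      state$cough_count_today <- state$cough_count_today + 1L
    }
    state$prev_prediction <- pred
    state$current_activity <- pred
    msgs[[i]] <- activity_message(t_i, pred, state$fall_latched)
  }
  log <- bind_rows(msgs)
  log$prediction <- preds
  if ("label" %in% names(stream)) log$label <- as.character(stream$label)
  summary <- list(cough_episodes = state$cough_count_today,
                  fall_latched = state$fall_latched,
                  first_fall_t = first_fall_t, n_samples = n)
  attr(log, "summary") <- summary
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      writeLines(jsonlite::toJSON(as.list(log[i, setdiff(names(log),
                                                         c("prediction",
                                                           "label"))]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
    writeLines(jsonlite::toJSON(c(list(summary = TRUE), summary),
                                auto_unbox = TRUE, digits = NA), con)
  }
  log
}
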