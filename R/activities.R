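#' Activity labels and the normal/abnormal taxonomy
#'
#' The system recognises five leaf activities from a chest-worn accelerometer:
#' `cough`, `fall`, `sit`, `walk` and `sleep`. Two of them signal risk events
#' (`cough`, `fall`) and are grouped as *abnormal*; the remaining three
#' (`sit`, `walk`, `sleep`) are *normal* daily activities. The cascade trains
#' its first model on this two-group relabelling and routes each prediction to
#' a sub-model specialised on one group.
#'
#' @return `activity_levels()` returns the character vector of the five leaf
#'   labels, in canonical order. `activity_taxonomy()` returns a tibble with
#'   columns `activity` and `group` mapping every leaf label to `"normal"` or
#'   `"abnormal"`.
#' @examples
#' activity_levels()
#' activity_taxonomy()
#' @export
activity_levels <- function() {
  c("cough", "fall", "sit", "walk", "sleep")
}

#' @rdname activity_levels
#' @export
activity_taxonomy <- function() {
  tibble(
    activity = activity_levels(),
    group = unname(c("cough" = "abnormal", "fall" = "abnormal",
                     "sit" = "normal", "walk" = "normal",
                     "sleep" = "normal")[activity_levels()])
  )
}

#' Map leaf activity labels to their taxonomy group
#'
#' @param labels character vector (or factor) of leaf activity labels.
#' @param taxonomy a taxonomy tibble as returned by [activity_taxonomy()].
#'   The default is the fixed normal/abnormal grouping; supplying a different
#'   two-group mapping generalises the cascade to other label trees.
#' @return character vector of group labels, same length as `labels`.
#' @export
activity_group <- function(labels, taxonomy = activity_taxonomy()) {
  labels <- as.character(labels)
  check_activity_labels(labels, allowed = taxonomy$activity)
  setNames(taxonomy$group, taxonomy$activity)[labels]
}

check_activity_labels <- function(labels, allowed = activity_levels()) {
  bad <- setdiff(unique(as.character(labels)), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown activity label(s): %s", paste(bad, collapse = ", ")),
          class = "harcascade_invalid_label")
  }
  invisible(labels)
}

as_activity_factor <- function(labels) {
  factor(as.character(labels), levels = activity_levels())
}
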