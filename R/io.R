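#' Read and write acceleration streams
#'
#' Streams are exchanged as CSV with header `t,x,y,z,label` (`t` in seconds,
#' axes in g, `label` one of the five activity strings) or as JSON Lines with
#' the same keys, one object per sample. The format is chosen by file
#' extension (`.jsonl`/`.ndjson` vs anything else = CSV). Unlabelled streams
#' (prediction input) simply omit the `label` column/key.
#'
#' @param path file path.
#' @param stream a data frame with columns `t`, `x`, `y`, `z` and optionally
#'   `label`.
#' @return `read_accel()` returns a tibble; `write_accel()` returns `path`
#'   invisibly.
#' @export
read_accel <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "harcascade_io_error")
  }
  df <- if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      tibble(t = double(), x = double(), y = double(), z = double())
    } else {
      rows <- purrr::imap(lines, function(l, i) {
        parsed <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
        if (is.null(parsed) || !all(c("t", "x", "y", "z") %in% names(parsed))) {
          abort(sprintf("malformed JSONL row at line %d of %s", i, path),
                class = "harcascade_parse_error")
        }
        as_tibble(parsed[intersect(c("t", "x", "y", "z", "label"),
                                   names(parsed))])
      })
      bind_rows(rows)
    }
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  req <- c("t", "x", "y", "z")
  if (nrow(df) > 0 && !all(req %in% names(df))) {
    abort(sprintf("%s lacks required columns t,x,y,z", path),
          class = "harcascade_parse_error")
  }
  as_tibble(df)
}

#' @rdname read_accel
#' @export
write_accel <- function(stream, path) {
  cols <- intersect(c("t", "x", "y", "z", "label"), names(stream))
  df <- as_tibble(stream)[cols]
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read and write feature tables
#'
#' CSV with the nine feature columns of [feature_names()] plus an optional
#' `label` column (and an optional `t` column, kept when present).
#'
#' @param path file path.
#' @param features a feature table as produced by [featurize_stream()].
#' @return `read_features()` returns a tibble; `write_features()` returns
#'   `path` invisibly.
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0) {
    abort(sprintf("feature table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "harcascade_parse_error")
  }
  as_tibble(df)
}

#' @rdname read_features
#' @export
write_features <- function(features, path) {
  cols <- intersect(c("t", feature_names(), "label"), names(features))
  readr::write_csv(as_tibble(features)[cols], path, progress = FALSE)
  invisible(path)
}
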