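#' Save and load fitted models
#'
#' A cascade is persisted as a directory holding one serialised file per
#' sub-model (`binary.rds`, `normal.rds`, `abnormal.rds`) plus a
#' `manifest.yaml` recording the format version, model kind, taxonomy,
#' per-model algorithm/seed and the feature order the models expect. A flat
#' model uses the same layout with a single `model.rds`. The manifest makes
#' the directory self-describing for other tools; the `.rds` payloads are R
#' serialisations.
#'
#' @param model a `har_cascade` or `har_flat`.
#' @param dir directory to create/overwrite.
#' @return `save_model()` returns `dir` invisibly; `load_model()` returns
#'   the restored model object.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "har_cascade")) {
    for (nm in names(model$models)) {
      saveRDS(model$models[[nm]], file.path(dir, paste0(nm, ".rds")))
    }
    manifest <- list(
      format_version = 1L, kind = "cascade",
      features = model$features,
      taxonomy = as.list(setNames(model$taxonomy$group,
                                  model$taxonomy$activity)),
      models = purrr::map(model$specs, function(s) {
        list(algorithm = s$algorithm, seed = s$seed)
      })
    )
  } else if (inherits(model, "har_flat")) {
    saveRDS(model$model, file.path(dir, "model.rds"))
    manifest <- list(format_version = 1L, kind = "flat",
                     features = model$features,
                     models = list(model = list(
                       algorithm = model$spec$algorithm,
                       seed = model$spec$seed)))
  } else {
    abort("model must be a har_cascade or har_flat",
          class = "harcascade_invalid_input")
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) {
    abort(sprintf("no manifest.yaml in %s", dir),
          class = "harcascade_io_error")
  }
  mf <- yaml::read_yaml(mf_path)
  if (!identical(mf$format_version, 1L) && !identical(mf$format_version, 1)) {
    abort("unsupported model format version", class = "harcascade_io_error")
  }
  if (mf$kind == "cascade") {
    models <- purrr::map(setNames(nm = c("binary", "normal", "abnormal")),
                         function(nm) readRDS(file.path(dir,
                                                        paste0(nm, ".rds"))))
    taxonomy <- tibble(activity = names(mf$taxonomy),
                       group = unlist(mf$taxonomy, use.names = FALSE))
    structure(list(models = models, taxonomy = taxonomy,
                   specs = purrr::map(models, "spec"),
                   features = unlist(mf$features)),
              class = "har_cascade")
  } else {
    model <- readRDS(file.path(dir, "model.rds"))
    structure(list(model = model, spec = model$spec,
                   features = unlist(mf$features)),
              class = "har_flat")
  }
}
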