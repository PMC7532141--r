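#' Save / load a model checkpoint
#'
#' Checkpoints carry the full parameter set together with the architectural
#' configuration and initialization seed, so a loaded model is usable (and
#' re-buildable) without external context.
#'
#' @param model A `ddx_model`.
#' @param path Destination file (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ddx_model")) stop("'model' must be a ddx_model", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ddx_model"))
    stop("file does not contain a ddx_model checkpoint", call. = FALSE)
  model
}

#' Read / write a flat YAML configuration
#'
#' One file drives the model, training and preprocessing settings. Keys
#' under `model:` are passed to [model_config()], keys under `train:` to
#' [train_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param config Named list, e.g. `list(model = list(...), train = list(...))`.
#' @return `read_config` returns a list with elements `model`
#'   (`ddx_config`) and `train` (`train_config`); missing sections fall
#'   back to defaults (the model section is required).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model))
    stop("config must contain a 'model' section", call. = FALSE)
  check_args <- function(given, fn, section) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown %s config key(s): %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_args(raw$model, model_config, "model")
  model <- do.call(model_config, raw$model)
  train_args <- if (is.null(raw$train)) list() else raw$train
  check_args(train_args, train_config, "train")
  list(model = model, train = do.call(train_config, train_args))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Featurized tensors: RDS archive + JSON sidecar describing shapes/metadata.
write_featurized <- function(data, path, meta = list()) {
  saveRDS(data, path)
  dm <- if (!is.null(data$x)) dim(data$x) else NULL
  side <- c(list(format = "ddxnet-featurized", shape = dm,
                 n_samples = if (!is.null(dm)) dm[length(dm)] else NA),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_featurized <- function(path) readRDS(path)
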