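# Saving and loading trained models: weights in R's native serialization,
# with a JSON sidecar recording the architecture and seed so a saved model
# is self-describing.

#' Save a trained model
#'
#' Writes the model object via `saveRDS()` and a human-readable JSON
#' sidecar (`<path>.json`) with the architecture, parameter count and
#' seed.
#'
#' @param model `mlp_model`.
#' @param path Destination file (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  saveRDS(model, path)
  sidecar <- list(n_features = model$spec$n_features,
                  hidden_sizes = model$spec$hidden_sizes,
                  use_regularization = model$spec$use_regularization,
                  activation = model$spec$activation,
                  n_params = n_params(model),
                  seed = model$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Verifies the weights against the JSON sidecar when present.
#'
#' @param path File written by [save_model()].
#' @return `mlp_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mlp_model")) stop(path, " does not hold an mlp_model")
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!identical(as.integer(sc$hidden_sizes), model$spec$hidden_sizes) ||
        sc$n_features != model$spec$n_features) {
      stop("sidecar ", sidecar_path, " does not match the saved weights")
    }
  }
  model
}

#' Export an interaction graph to GraphML
#'
#' @param graph `interaction_graph` (or igraph object).
#' @param path Output `.graphml` file.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
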