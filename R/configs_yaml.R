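# YAML round-trip for the three run configurations, so experiments can be
# described by a single file (model / codec / train sections, field names
# matching the constructor arguments).

#' Read run configurations from a YAML file
#'
#' The file may contain any of the sections `model`, `codec`, `train`;
#' each present section is passed as arguments to [backbone_config()],
#' [codec_config()] and [train_config()] respectively. `train$lr_drops` is
#' given as a mapping from epoch to rate.
#'
#' @param path YAML file.
#' @return list with elements `model`, `codec`, `train` (those present).
#' @export
configs_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$model)) out$model <- do.call(backbone_config, y$model)
  if (!is.null(y$codec)) {
    for (f in c("input_size", "heatmap_size")) {
      if (!is.null(y$codec[[f]])) y$codec[[f]] <- unlist(y$codec[[f]])
    }
    out$codec <- do.call(codec_config, y$codec)
  }
  if (!is.null(y$train)) {
    if (!is.null(y$train$lr_drops)) {
      y$train$lr_drops <- unlist(y$train$lr_drops)
    }
    out$train <- do.call(train_config, y$train)
  }
  out
}

#' Write run configurations to a YAML file
#'
#' @param path output file.
#' @param model,codec,train optional configuration objects.
#' @return the path, invisibly.
#' @export
configs_to_yaml <- function(path, model = NULL, codec = NULL, train = NULL) {
  y <- list()
  if (!is.null(model)) y$model <- unclass(model)
  if (!is.null(codec)) y$codec <- unclass(codec)
  if (!is.null(train)) {
    tr <- unclass(train)
    if (length(tr$lr_drops)) tr$lr_drops <- as.list(tr$lr_drops)
    y$train <- tr
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
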