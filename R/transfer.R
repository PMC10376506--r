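#' Transfer strategies: which stages are retrained
#'
#' Encodes the freeze/retrain mask applied when fine-tuning a pretrained
#' backbone. The heatmap head is always retrained (it is randomly
#' re-initialized on load). The stem is grouped with stage 1 for freezing:
#' it precedes stage 1 and is a general feature extractor by the same
#' reasoning that freezes low stages.
#'
#' * `TH`: all four stages frozen, only the head trains.
#' * `TS`: stem and stage 1 frozen; stages 2-4 and the head train.
#' * `TA`: everything trains.
#' * `custom`: supply `mask`, a named logical over
#'   `c("stem","stage1","stage2","stage3","stage4","head")` (intermediate
#'   variants, e.g. only stage 4 retrained, are expressed this way).
#'
#' @param name one of `"TH"`, `"TS"`, `"TA"`, `"custom"`.
#' @param mask named logical vector, required when `name == "custom"`;
#'   `TRUE` means retrained. All groups must be named explicitly except
#'   `head`, which defaults to `TRUE` and must not be `FALSE`.
#' @return a `transfer_strategy` object.
#' @export
transfer_strategy <- function(name = c("TS", "TH", "TA", "custom"),
                              mask = NULL) {
  name <- match.arg(name)
  groups <- c("stem", "stage1", "stage2", "stage3", "stage4", "head")
  m <- switch(name,
    TH = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    TS = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    TA = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    custom = {
      if (is.null(mask) || is.null(names(mask))) {
        stop("custom strategy requires a named logical mask")
      }
      unknown <- setdiff(names(mask), groups)
      if (length(unknown)) {
        stop("unknown parameter group(s) in mask: ",
             paste(unknown, collapse = ", "))
      }
      if (!is.na(mask["head"]) && identical(unname(mask["head"]), FALSE)) {
        stop("the heatmap head is always trainable")
      }
      full <- stats::setNames(rep(NA, 6), groups)
      full[names(mask)] <- mask
      if (is.na(full["head"])) full["head"] <- TRUE
      if (anyNA(full)) {
        stop("custom mask must cover groups: ",
             paste(groups[is.na(full)], collapse = ", "))
      }
      as.logical(full)
    })
  structure(list(name = name, mask = stats::setNames(as.logical(m), groups)),
            class = "transfer_strategy")
}

#' Apply a freeze/retrain strategy to a model
#'
#' Parameters in groups with `mask = FALSE` are excluded from optimizer
#' updates; batch-norm layers in frozen groups also stop updating running
#' statistics and normalize with them (evaluation-mode statistics), so a
#' retained stage cannot adapt covertly through its normalization state.
#'
#' @param model a `wm_model`.
#' @param strategy a [transfer_strategy()].
#' @param freeze_bn_stats logical; freeze normalization statistics of frozen
#'   groups (default `TRUE`).
#' @return the model, invisibly (modified in place).
#' @export
apply_strategy <- function(model, strategy, freeze_bn_stats = TRUE) {
  stopifnot(inherits(strategy, "transfer_strategy"))
  model$trainable_mask <- strategy$mask
  model$strategy <- strategy
  for (ly in model$bn_layers) {
    ly$frozen <- freeze_bn_stats && !strategy$mask[[ly$group]]
  }
  invisible(model)
}

#' Trainable parameters under the model's current strategy
#' @param model a `wm_model`.
#' @return named list of parameter tensors.
#' @export
trainable_params <- function(model) {
  keep <- model$trainable_mask[model$group_of[names(model$params)]]
  model$params[keep]
}

#' Load pretrained backbone weights with a randomly re-initialized head
#'
#' Copies all backbone-group entries (parameters and batch-norm running
#' statistics) from a checkpoint state into the model, then re-initializes
#' the heatmap head from normal(0, 0.001) weights and zero biases under a
#' recorded seed. Head entries present in the checkpoint are ignored with a
#' warning; a shape mismatch in any backbone entry aborts, naming the group
#' and entry.
#'
#' @param model a `wm_model`.
#' @param checkpoint a state list from [model_state()]/[load_checkpoint()],
#'   or a file path.
#' @param head_seed integer seed for head re-initialization.
#' @param strict_backbone if `TRUE` (default), every backbone entry of the
#'   model must be present in the checkpoint.
#' @return the model, invisibly (modified in place).
#' @export
load_pretrained <- function(model, checkpoint, head_seed = 1,
                            strict_backbone = TRUE) {
  state <- if (is.character(checkpoint)) load_checkpoint(checkpoint)
           else checkpoint
  head_nms <- names(state$groups)[state$groups == "head"]
  if (length(head_nms)) {
    warning("checkpoint contains ", length(head_nms),
            " head entries; ignored (head is randomly re-initialized)")
  }
  backbone_nms <- setdiff(names(state$arrays), head_nms)
  own_state <- model_state(model)
  own_backbone <- names(own_state$groups)[own_state$groups != "head"]
  if (strict_backbone) {
    missing <- setdiff(own_backbone, backbone_nms)
    if (length(missing)) {
      stop("checkpoint is missing backbone entries, e.g. ", missing[1])
    }
  }
  for (nm in intersect(backbone_nms, own_backbone)) {
    v <- state$arrays[[nm]]
    have <- own_state$arrays[[nm]]
    if (!identical(dim2(have), dim2(v))) {
      stop(sprintf("shape mismatch in group '%s' for entry '%s'",
                   state$groups[[nm]], nm))
    }
  }
  set_model_state(model, list(arrays = state$arrays[
    intersect(backbone_nms, own_backbone)]))
  reinit_head(model, head_seed)
  model$head_init_seed <- head_seed
  invisible(model)
}

reinit_head <- function(model, seed) {
  set.seed(seed)
  w <- model$head$w
  w$value <- matrix(stats::rnorm(length(w$value), 0, 0.001),
                    nrow(w$value), ncol(w$value))
  if (!is.null(model$head$b)) model$head$b$value <- numeric(length(model$head$b$value))
  invisible(model)
}
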