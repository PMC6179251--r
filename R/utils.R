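# Internal condition helpers: input errors (bad user data) are distinguished
# from degenerate-data errors (valid input on which the method is undefined)
# so callers, including the command-line wrapper, can react differently.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("sctransfer_input_error", "error", "condition")))
}

stop_degenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("sctransfer_degenerate_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyperparameters for the boosted-tree classifier
#'
#' The fixed, pre-tuned gradient-boosting settings used for every model:
#' learning rate (`eta`) 0.7, 20 boosting rounds, minimum split gain
#' (`gamma`) 0.001, maximum tree depth 5 and minimum child weight 10.
#' They are deliberately not tuned per dataset; consistency across datasets
#' is part of the method's design.
#'
#' @return Named list of hyperparameter values.
#' @export
default_hyperparameters <- function() {
  list(eta = 0.7, nround = 20, gamma = 0.001, max_depth = 5,
       min_child_weight = 10)
}

#' Labels excluded from training
#'
#' Cell annotations that mark a cell as unusable ground truth. Cells carrying
#' one of these labels (or any label containing "contaminated",
#' case-insensitively) are dropped when a dataset is used as a training
#' source, but kept when it is classified as a target, where recovering a
#' confident label for them is itself informative.
#'
#' @return Character vector of excluded label strings.
#' @export
default_excluded_labels <- function() {
  c("unknown", "not applicable", "unclassified")
}

#' Flag cells whose label is excluded from training
#'
#' @param labels Character vector of per-cell labels.
#' @param excluded Labels treated as unusable (exact, case-insensitive match).
#' @return Logical vector, `TRUE` where the label is excluded.
#' @export
is_excluded_label <- function(labels, excluded = default_excluded_labels()) {
  low <- tolower(as.character(labels))
  low %in% tolower(excluded) | grepl("contaminated", low, fixed = TRUE)
}
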