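# Evaluation measures: overall accuracy, one-vs-rest binary metrics
# (sensitivity, specificity, precision, rank-based ROC AUC), the
# majority-vote transfer baseline, and a combined per-type report.

#' Classification accuracy
#'
#' Percentage of cells whose predicted label equals the true label. By
#' default, cells whose *true* label is in the excluded set
#' (unknown/contaminated/...) are dropped from the denominator — they are
#' unusable ground truth, not errors. `"unknown"` *predictions* on cells
#' with usable truth count as incorrect.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param excluded True labels dropped from the denominator; set to
#'   `character(0)` to include every cell.
#' @return Percent in \[0, 100\].
#' @export
accuracy <- function(truth, predicted, excluded = default_excluded_labels()) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_input("truth and predicted differ in length (%d vs %d)",
               length(truth), length(predicted))
  if (!length(truth)) stop_input("empty label vectors")
  keep <- !is_excluded_label(truth, excluded)
  if (!any(keep))
    stop_input("no cells with usable ground-truth labels")
  100 * mean(truth[keep] == predicted[keep])
}

#' Rank-based ROC AUC
#'
#' Area under the receiver operating characteristic curve via the
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive outranks a random negative, counting ties as one half.
#'
#' @param truth_indicator 0/1 (or logical) vector.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC as a percent in \[0, 100\].
#' @export
roc_auc <- function(truth_indicator, scores) {
  pos <- as.logical(as.integer(truth_indicator))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_input("AUC requires at least one positive and one negative instance")
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binary classification metrics at a score cut
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
#' `TP/(TP+FP)` at the given score cut, plus the threshold-free rank-based
#' AUC, all as percents. Ratios with a zero denominator are `NA`.
#'
#' Note on naming: some reports describe "specificity" as the share of true
#' positives among cells *classified as* the type — that is precision under
#' the textbook definitions used here. Both are returned so either reporting
#' convention can be served unambiguously.
#'
#' @param truth_indicator 0/1 (or logical) vector.
#' @param scores Scores in \[0, 1\].
#' @param cut Score at or above which a cell is called positive.
#' @return Named list: `sensitivity`, `specificity`, `precision`, `auc`
#'   (percents).
#' @export
binary_metrics <- function(truth_indicator, scores, cut = 0.5) {
  pos <- as.logical(as.integer(truth_indicator))
  if (length(pos) != length(scores))
    stop_input("indicator and scores differ in length")
  if (any(scores < 0 | scores > 1))
    stop_input("scores must lie in [0, 1]")
  if (all(pos) || all(!pos))
    stop_input("metrics require both positive and negative instances")
  call_pos <- scores >= cut
  tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
  tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp),
       auc = roc_auc(pos, scores))
}

#' Majority-vote baseline accuracy
#'
#' The accuracy of the trivial transfer classifier that labels every target
#' cell with the source dataset's most frequent class — the lower bound any
#' transferred model must beat. Ties among source majority classes are
#' broken lexicographically.
#'
#' @param source_labels,target_labels Label vectors.
#' @return Percent of target cells belonging to the source majority class.
#' @export
majority_vote_accuracy <- function(source_labels, target_labels) {
  source_labels <- as.character(source_labels)
  target_labels <- as.character(target_labels)
  if (!length(source_labels) || !length(target_labels))
    stop_input("empty label vectors")
  counts <- table(source_labels)
  majority <- sort(names(counts)[counts == max(counts)])[1]
  100 * mean(target_labels == majority)
}

#' Per-type evaluation report
#'
#' Confusion matrix, overall accuracy and one-vs-rest per-type metrics for
#' a predicted labeling, optionally with per-type AUC when membership
#' scores are available and class-share columns when source labels are
#' given.
#'
#' @param truth,predicted Label vectors over the same cells.
#' @param scores Optional [score_matrix()] (or matrix) with one column per
#'   type, for AUC.
#' @param source_labels Optional source label vector, to report per-type
#'   source shares.
#' @param excluded True labels dropped from accuracy and the per-type rows.
#' @param specificity_as_precision If `TRUE`, the per-type table's `specificity` column
#'   carries precision (the share of true positives among cells classified
#'   as the type), matching reports that use that wording; the standard
#'   rate is then in `specificity_std`.
#' @return Object of class `evaluation_report`: `accuracy_pct`, `per_type`
#'   data frame, `confusion` table.
#' @export
evaluation_report <- function(truth, predicted, scores = NULL,
                              source_labels = NULL,
                              excluded = default_excluded_labels(),
                              specificity_as_precision = FALSE) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_input("truth and predicted differ in length")
  keep <- !is_excluded_label(truth, excluded)
  tr <- truth[keep]; pr <- predicted[keep]
  lev <- sort(union(tr, pr))
  confusion <- table(truth = factor(tr, lev), predicted = factor(pr, lev))
  sm <- if (inherits(scores, "score_matrix")) scores$scores else scores
  types <- sort(setdiff(unique(tr), "unknown"))
  rows <- lapply(types, function(ty) {
    pos <- tr == ty
    call_pos <- pr == ty
    tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
    tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
    ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    auc <- if (!is.null(sm) && ty %in% colnames(sm) && any(pos) && any(!pos))
      roc_auc(pos, sm[keep, ty]) else NA_real_
    data.frame(type = ty,
               n_target_pct = 100 * mean(pos),
               n_source_pct = if (is.null(source_labels)) NA_real_ else
                 100 * mean(as.character(source_labels) == ty),
               sensitivity = ratio(tp, tp + fn),
               specificity = ratio(tn, tn + fp),
               precision = ratio(tp, tp + fp),
               auc = auc, stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, rows)
  if (isTRUE(specificity_as_precision) && !is.null(per_type)) {
    per_type$specificity_std <- per_type$specificity
    per_type$specificity <- per_type$precision
  }
  structure(list(accuracy_pct = 100 * mean(tr == pr),
                 per_type = per_type, confusion = confusion,
                 n_evaluated = sum(keep), n_excluded = sum(!keep)),
            class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy: %.1f%% over %d cells (%d excluded from evaluation)\n",
              x$accuracy_pct, x$n_evaluated, x$n_excluded))
  if (!is.null(x$per_type)) {
    df <- x$per_type
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the per-type table as CSV, the whole report as JSON, and the
#' confusion matrix as CSV.
#'
#' @param report An [evaluation_report()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(csv = file.path(dir, paste0(prefix, "_per_type.csv")),
             json = file.path(dir, paste0(prefix, ".json")),
             confusion = file.path(dir, paste0(prefix, "_confusion.csv")))
  if (!is.null(report$per_type))
    utils::write.csv(report$per_type, paths["csv"], row.names = FALSE)
  jsonlite::write_json(list(accuracy_pct = report$accuracy_pct,
                            n_evaluated = report$n_evaluated,
                            n_excluded = report$n_excluded,
                            per_type = report$per_type),
                       paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(as.data.frame.matrix(report$confusion), paths["confusion"])
  invisible(paths)
}
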