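# Gradient-boosted tree classification on the engineered ordinal features.
# The booster consumes the bin codes 0-3 directly as ordinal integers; trees
# split ordinals natively, so no one-hot encoding is performed.

# Stratified split: within every class, a random train_frac share (at least
# one cell) goes to training. Returns training row indices.
stratified_train_idx <- function(labels, train_frac, seed) {
  set.seed(seed)
  idx <- integer(0)
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    n_tr <- max(1L, round(train_frac * length(rows)))
    if (n_tr == length(rows) && length(rows) > 1L) n_tr <- length(rows) - 1L
    idx <- c(idx, sort(sample(rows, n_tr)))
  }
  sort(idx)
}

#' Train the boosted-tree classifier on a source dataset
#'
#' Trains on a stratified random `train_frac` share of the source cells with
#' the fixed, pre-tuned hyperparameters, and evaluates on the held-out
#' remainder. The multiclass objective is softmax with per-class
#' probabilities; per-type binary classifiers use the logistic objective, so
#' scores are class-membership probabilities in \[0, 1\] in both modes.
#' Training is single-threaded and seeded, so identical inputs and seed give
#' identical models.
#'
#' @param source_binned A [binned_matrix()] of the source cells.
#' @param labels Per-cell class labels; in binary mode a 0/1 indicator
#'   (or the model is trained for `mode = "binary:<type>"` with labels
#'   already converted).
#' @param mode `"multiclass"` or `"binary:<type>"`.
#' @param hyperparameters See [default_hyperparameters()].
#' @param train_frac Share of cells used for training (default 0.8).
#' @param seed Integer seed controlling the split and training.
#' @param fs Optional [feature_set()] stored with the model.
#' @return List with `model` (class `sctransfer_model`) and
#'   `heldout_accuracy` (percent correct on the held-out cells, `NA` if the
#'   held-out set is empty).
#' @export
train_model <- function(source_binned, labels, mode = "multiclass",
                        hyperparameters = default_hyperparameters(),
                        train_frac = 0.8, seed = 1, fs = NULL) {
  codes <- source_binned$codes
  labels <- as.character(labels)
  if (length(labels) != nrow(codes))
    stop_input("labels length (%d) does not match cell count (%d)",
               length(labels), nrow(codes))
  binary <- startsWith(mode, "binary")
  class_order <- sort(unique(labels))
  if (length(class_order) < 2)
    stop_input("training requires at least two classes, got %d",
               length(class_order))
  if (binary && !setequal(class_order, c("0", "1")))
    stop_input("binary mode requires a 0/1 indicator label vector")
  if (binary) class_order <- c("0", "1")

  tr <- stratified_train_idx(labels, train_frac, seed)
  te <- setdiff(seq_len(nrow(codes)), tr)
  y_num <- match(labels, class_order) - 1L
  if (length(unique(y_num[tr])) < length(class_order))
    stop_input("a class is absent from the training split; classes with a single cell cannot be stratified at train_frac = %g",
               train_frac)

  params <- list(eta = hyperparameters$eta, gamma = hyperparameters$gamma,
                 max_depth = hyperparameters$max_depth,
                 min_child_weight = hyperparameters$min_child_weight,
                 nthread = 1, seed = seed)
  if (binary) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- length(class_order)
  }
  dtrain <- xgboost::xgb.DMatrix(codes[tr, , drop = FALSE],
                                 label = y_num[tr], nthread = 1)
  set.seed(seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyperparameters$nround, verbose = 0)

  model <- structure(list(booster = booster,
                          feature_ids = source_binned$feature_ids,
                          edges = source_binned$edges,
                          class_order = class_order, mode = mode,
                          hyperparameters = hyperparameters,
                          train_seed = seed, feature_set = fs),
                     class = "sctransfer_model")

  heldout_accuracy <- NA_real_
  if (length(te)) {
    sm <- predict(model, binned_matrix(codes[te, , drop = FALSE],
                                       source_binned$feature_ids,
                                       source_binned$edges))
    if (binary) {
      heldout_accuracy <- 100 * mean((sm$scores[, 1] >= 0.5) ==
                                       (labels[te] == "1"))
    } else {
      pred <- assign_with_threshold(sm, threshold = 0)
      heldout_accuracy <- 100 * mean(pred == labels[te])
    }
  }
  list(model = model, heldout_accuracy = heldout_accuracy)
}

# Column name used for the positive-class score of a binary model.
model_positive_name <- function(model) {
  if (model$mode == "multiclass") return(NULL)
  nm <- sub("^binary:?", "", model$mode)
  if (nzchar(nm)) nm else "1"
}

#' @exportS3Method base::print
print.sctransfer_model <- function(x, ...) {
  cat(sprintf("sctransfer_model (%s): %d features, classes: %s\n", x$mode,
              length(x$feature_ids),
              paste(x$class_order, collapse = ", ")))
  invisible(x)
}

#' Score target cells with a trained model
#'
#' @param object A trained `sctransfer_model`.
#' @param target_binned A [binned_matrix()] over exactly the model's
#'   features, in order.
#' @param ... Unused.
#' @return A `score_matrix`: cells x types membership scores in \[0, 1\].
#'   Multiclass rows sum to 1; a binary model yields a single column named
#'   after its positive type.
#' @export
predict.sctransfer_model <- function(object, target_binned, ...) {
  if (!identical(object$feature_ids, target_binned$feature_ids)) {
    missing <- setdiff(object$feature_ids, target_binned$feature_ids)
    extra <- setdiff(target_binned$feature_ids, object$feature_ids)
    stop_input("target features do not match the model (missing: %s; extra: %s; order must match)",
               paste(utils::head(missing, 5), collapse = ",") %||% "",
               paste(utils::head(extra, 5), collapse = ","))
  }
  dm <- xgboost::xgb.DMatrix(target_binned$codes, nthread = 1)
  p <- predict(object$booster, dm)
  if (object$mode == "multiclass") {
    scores <- matrix(p, nrow = nrow(target_binned$codes),
                     ncol = length(object$class_order))
    colnames(scores) <- object$class_order
  } else {
    scores <- matrix(p, ncol = 1,
                     dimnames = list(NULL, model_positive_name(object)))
  }
  rownames(scores) <- rownames(target_binned$codes)
  score_matrix(scores)
}

#' Construct a score matrix
#'
#' @param scores Numeric cells x types matrix of membership scores in
#'   \[0, 1\], with cell ids as row names and type ids as column names.
#' @return Object of class `score_matrix`.
#' @export
score_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (any(scores < -1e-9 | scores > 1 + 1e-9))
    stop_input("scores must lie in [0, 1]")
  structure(list(scores = scores,
                 cell_ids = rownames(scores) %||%
                   paste0("C", seq_len(nrow(scores))),
                 type_ids = colnames(scores) %||%
                   paste0("T", seq_len(ncol(scores)))),
            class = "score_matrix")
}

#' @exportS3Method base::print
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d cells x %d types\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Assign labels from scores, flagging unknown cells
#'
#' Each cell receives the type with its largest score, provided that score
#' reaches `threshold`; otherwise the cell is labeled `"unknown"`. Cells
#' whose best score stays below the threshold are candidates for cell types
#' absent from the source dataset. Ties on the maximum are broken by type-id
#' (column) order.
#'
#' @param scores A [score_matrix()] or plain cells x types matrix.
#' @param threshold Minimum score for an assignment (default 0.8).
#' @param unknown_label Label used for sub-threshold cells.
#' @return Character vector of per-cell labels.
#' @export
assign_with_threshold <- function(scores, threshold = 0.8,
                                  unknown_label = "unknown") {
  m <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  if (!ncol(m)) stop_input("score matrix has no type columns")
  best <- max.col(m, ties.method = "first")
  best_score <- m[cbind(seq_len(nrow(m)), best)]
  out <- colnames(m)[best]
  out[best_score < threshold] <- unknown_label
  out
}

#' Save a trained model bundle
#'
#' Writes a directory containing the booster dump (`model.ubj`), the feature
#' set (`featureset.json`) and run metadata (`metadata.json`), sufficient to
#' re-apply the model to a new target.
#'
#' @param model A `sctransfer_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.ubj"))
  jsonlite::write_json(list(mode = model$mode,
                            class_order = model$class_order,
                            feature_ids = model$feature_ids,
                            edges = model$edges,
                            hyperparameters = model$hyperparameters,
                            train_seed = model$train_seed),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(model$feature_set))
    write_feature_set(model$feature_set, file.path(dir, "featureset.json"))
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#'
#' @param dir Bundle directory.
#' @return A `sctransfer_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  fs_path <- file.path(dir, "featureset.json")
  structure(list(booster = xgboost::xgb.load(file.path(dir, "model.ubj")),
                 feature_ids = meta$feature_ids, edges = meta$edges,
                 class_order = meta$class_order, mode = meta$mode,
                 hyperparameters = as.list(meta$hyperparameters),
                 train_seed = meta$train_seed,
                 feature_set = if (file.exists(fs_path))
                   read_feature_set(fs_path) else NULL),
            class = "sctransfer_model")
}

# Shared preamble of the transfer runs: drop excluded-label source cells.
usable_source <- function(source, excluded) {
  keep <- !is_excluded_label(source$labels, excluded)
  if (!any(keep))
    stop_input("no usable source cells after excluding labels: %s",
               paste(excluded, collapse = ", "))
  ds_subset(source, cells = keep)
}

#' Multiclass transfer run
#'
#' The full workflow under the assumption that the source contains every
#' target cell type: features are engineered once on the full source +
#' target pair, then `n_repeats` models are trained, each on a stratified
#' random 80% of the source, and evaluated twice — on the held-out 20% and
#' on the whole target. Repeats differ only in the split seed
#' (`base_seed`, `base_seed + 1`, ...). The majority-vote baseline (every
#' target cell assigned the source's most frequent class) is reported
#' alongside. Target cells whose true label is excluded
#' (unknown/contaminated/...) are classified but omitted from the accuracy
#' denominator.
#'
#' @param source,target [gene_expression_dataset()] objects on log2 scale.
#' @param n_repeats Number of split/train repeats (default 10).
#' @param base_seed Seed of the first repeat.
#' @param threshold Optional score threshold; by default every cell is
#'   assigned its argmax class.
#' @param excluded Labels excluded from source training and target
#'   evaluation.
#' @inheritParams engineer_features
#' @param hyperparameters See [default_hyperparameters()].
#' @param train_frac Training share of the source (default 0.8).
#' @return Object of class `transfer_result` with per-repeat held-out and
#'   target accuracies, their means/sds, the majority-vote baseline, the
#'   predicted labels (first repeat's model), scores, the feature set and
#'   the pipeline log.
#' @export
run_multiclass <- function(source, target, n_repeats = 10, base_seed = 1,
                           threshold = 0, excluded = default_excluded_labels(),
                           k_mean = 100, k_mi = k_mean, r_max = 0.9,
                           min_cells = 10, edges = c(0, 1, 6),
                           hyperparameters = default_hyperparameters(),
                           train_frac = 0.8) {
  src <- usable_source(source, excluded)
  eng <- engineer_features(src, target, src$labels, k_mean = k_mean,
                           k_mi = k_mi, r_max = r_max, min_cells = min_cells,
                           edges = edges)
  eval_mask <- !is_excluded_label(target$labels, excluded)
  if (!any(eval_mask))
    stop_input("no target cells with usable ground-truth labels")

  heldout <- target_acc <- numeric(n_repeats)
  first_scores <- NULL
  seeds <- base_seed + seq_len(n_repeats) - 1L
  for (i in seq_len(n_repeats)) {
    fit <- train_model(eng$source_binned, src$labels, mode = "multiclass",
                       hyperparameters = hyperparameters,
                       train_frac = train_frac, seed = seeds[i],
                       fs = eng$feature_set)
    heldout[i] <- fit$heldout_accuracy
    sm <- predict(fit$model, eng$target_binned)
    pred <- assign_with_threshold(sm, threshold = threshold)
    target_acc[i] <- accuracy(target$labels[eval_mask], pred[eval_mask],
                              excluded = excluded)
    if (i == 1L) first_scores <- sm
  }
  mv <- majority_vote_accuracy(src$labels, target$labels[eval_mask])
  structure(list(predicted_labels = assign_with_threshold(first_scores,
                                                          threshold = threshold),
                 scores = first_scores,
                 heldout_accuracy_runs = heldout,
                 target_accuracy_runs = target_acc,
                 heldout_mean = mean(heldout),
                 heldout_sd = if (n_repeats > 1) stats::sd(heldout) else NA_real_,
                 target_mean = mean(target_acc),
                 target_sd = if (n_repeats > 1) stats::sd(target_acc) else NA_real_,
                 majority_vote_accuracy = mv,
                 feature_set = eng$feature_set, log = eng$log,
                 seeds = seeds, mode = "multiclass"),
            class = "transfer_result")
}

#' @exportS3Method base::print
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result (%s, %d repeats)\n", x$mode, length(x$seeds)))
  cat(sprintf("  held-out accuracy: %.1f%% (sd %.2f)\n", x$heldout_mean,
              x$heldout_sd))
  cat(sprintf("  target accuracy:   %.1f%% (sd %.2f)\n", x$target_mean,
              x$target_sd))
  cat(sprintf("  majority vote:     %.1f%%\n", x$majority_vote_accuracy))
  invisible(x)
}

#' Per-cell-type binary transfer run with unknown detection
#'
#' Drops the assumption that the source covers every target type: the shared
#' preprocessing (gene alignment, rare-gene removal, pooled-mean selection)
#' runs once, then for every usable source cell type the label-dependent
#' steps (mutual-information selection, union, pruning, binning,
#' constant-bin removal, training) are re-run against a one-vs-rest 0/1
#' indicator. Each target cell collects one membership score per type and
#' is assigned by [assign_with_threshold()]: cells whose best score stays
#' below `threshold` are labeled `"unknown"` — candidates for types absent
#' from the source.
#'
#' @inheritParams run_multiclass
#' @param threshold Minimum best score for an assignment (default 0.8).
#' @param n_repeats Models per type; with more than one, target scores are
#'   averaged over the repeat models.
#' @return List with `scores` (a [score_matrix()], cells x source types),
#'   `predicted_labels` (with `"unknown"`), `heldout_accuracy` (named per
#'   type, first repeat), `skipped_types`, and `feature_sets` per type.
#' @export
run_per_type <- function(source, target, threshold = 0.8, n_repeats = 1,
                         base_seed = 1, excluded = default_excluded_labels(),
                         k_mean = 100, k_mi = k_mean, r_max = 0.9,
                         min_cells = 10, edges = c(0, 1, 6),
                         hyperparameters = default_hyperparameters(),
                         train_frac = 0.8) {
  src <- usable_source(source, excluded)
  al <- align_common_genes(src, target)
  fl <- filter_rare_genes(al$source, al$target, min_cells = min_cells)
  mean_ids <- top_k_ids(pooled_gene_means(fl$source, fl$target), k_mean)
  src_codes_all <- bin_values(fl$source$matrix, edges)

  types <- sort(unique(src$labels))
  skipped <- character(0)
  scores <- matrix(NA_real_, nrow(target$matrix), 0,
                   dimnames = list(target$cell_ids, NULL))
  heldout <- c()
  fsets <- list()
  for (ty in types) {
    indicator <- as.integer(src$labels == ty)
    if (sum(indicator) < 2 || sum(indicator == 0) < 2) {
      warning(sprintf("type '%s' has fewer than 2 positive or negative cells in the source; skipped", ty))
      skipped <- c(skipped, ty)
      next
    }
    mi_ids <- top_k_ids(mi_per_gene(src_codes_all$codes,
                                    as.character(indicator)), k_mi)
    priority <- c(mi_ids, setdiff(mean_ids, mi_ids))
    pool_vals <- rbind(fl$source$matrix[, priority, drop = FALSE],
                       fl$target$matrix[, priority, drop = FALSE])
    pr <- prune_correlated(pool_vals, priority, r_max = r_max)
    sb <- bin_values(fl$source$matrix[, pr$retained, drop = FALSE], edges)
    tb <- bin_values(fl$target$matrix[, pr$retained, drop = FALSE], edges)
    keep <- constant_bin_columns(rbind(sb$codes, tb$codes))
    if (!any(keep)) {
      warning(sprintf("type '%s': no informative features; skipped", ty))
      skipped <- c(skipped, ty)
      next
    }
    retained <- pr$retained[keep]
    sb <- binned_matrix(sb$codes[, retained, drop = FALSE], retained, edges)
    tb <- binned_matrix(tb$codes[, retained, drop = FALSE], retained, edges)
    dropped <- pr$dropped
    dropped[pr$retained[!keep]] <- "constant_bin"
    prov <- lapply(retained, function(g)
      c(if (g %in% mi_ids) "mi_selected", if (g %in% mean_ids) "mean_selected"))
    names(prov) <- retained
    fsets[[ty]] <- feature_set(retained, prov, edges, dropped,
                               params = list(k_mean = k_mean, k_mi = k_mi,
                                             r_max = r_max,
                                             min_cells = min_cells,
                                             type = ty))
    ty_scores <- matrix(0, nrow(target$matrix), n_repeats)
    for (i in seq_len(n_repeats)) {
      fit <- train_model(sb, as.character(indicator),
                         mode = paste0("binary:", ty),
                         hyperparameters = hyperparameters,
                         train_frac = train_frac,
                         seed = base_seed + i - 1L, fs = fsets[[ty]])
      ty_scores[, i] <- predict(fit$model, tb)$scores[, 1]
      if (i == 1L) heldout[ty] <- fit$heldout_accuracy
    }
    scores <- cbind(scores, rowMeans(ty_scores))
    colnames(scores)[ncol(scores)] <- ty
  }
  if (!ncol(scores))
    stop_degenerate("no source cell type could be trained")
  sm <- score_matrix(scores)
  list(scores = sm,
       predicted_labels = assign_with_threshold(sm, threshold = threshold),
       heldout_accuracy = heldout, skipped_types = skipped,
       feature_sets = fsets, threshold = threshold)
}
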