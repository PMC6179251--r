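# Reference benchmark: top-5 pooled-mean genes + one-vs-rest ordinary least
# squares on 0/1 class indicators, under the same 80/20 x repeats protocol
# as the boosted-tree workflow. Deliberately minimal: no binning, no
# correlation pruning — it represents the simplest robust baseline.

# OLS fit of y on cbind(1, X); falls back to a tiny ridge penalty when the
# design is rank deficient.
ols_fit <- function(X, y, ridge = 1e-8) {
  A <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(A, y)
  if (fit$rank < ncol(A) || anyNA(fit$coefficients)) {
    AtA <- crossprod(A) + diag(ridge, ncol(A))
    beta <- solve(AtA, crossprod(A, y))
    attr(beta, "ridge") <- TRUE
    return(drop(beta))
  }
  fit$coefficients
}

#' Top-mean linear-regression transfer benchmark
#'
#' Selects the `k` genes with the highest pooled mean expression across both
#' datasets and fits, per class, an ordinary least-squares regression of the
#' 0/1 class indicator on the continuous log-scale values of those genes
#' (one-against-all); the predicted class of a cell is the class with the
#' largest fitted value. Training uses the same stratified 80/20 split and
#' repeat protocol as [run_multiclass()] with identical seeds, so paired
#' accuracy comparisons between the two methods are valid.
#'
#' @inheritParams run_multiclass
#' @param k Number of top-mean genes (default 5).
#' @return A `transfer_result` (see [run_multiclass()]).
#' @export
benchmark_top_mean_linear <- function(source, target, k = 5, n_repeats = 10,
                                      base_seed = 1,
                                      excluded = default_excluded_labels(),
                                      train_frac = 0.8) {
  src <- usable_source(source, excluded)
  al <- align_common_genes(src, target)
  genes <- select_top_mean(al$source, al$target, k = k)
  Xs <- al$source$matrix[, genes, drop = FALSE]
  Xt <- al$target$matrix[, genes, drop = FALSE]
  classes <- sort(unique(src$labels))
  if (length(classes) < 2)
    stop_input("benchmark requires at least two source classes")
  eval_mask <- !is_excluded_label(target$labels, excluded)
  if (!any(eval_mask))
    stop_input("no target cells with usable ground-truth labels")

  predict_argmax <- function(B, X) {
    fitted <- cbind(1, X) %*% B
    classes[max.col(fitted, ties.method = "first")]
  }
  heldout <- target_acc <- numeric(n_repeats)
  first_pred <- NULL
  seeds <- base_seed + seq_len(n_repeats) - 1L
  for (i in seq_len(n_repeats)) {
    tr <- stratified_train_idx(src$labels, train_frac, seeds[i])
    te <- setdiff(seq_len(nrow(Xs)), tr)
    B <- vapply(classes, function(cl)
      ols_fit(Xs[tr, , drop = FALSE], as.numeric(src$labels[tr] == cl)),
      numeric(ncol(Xs) + 1))
    heldout[i] <- if (length(te))
      100 * mean(predict_argmax(B, Xs[te, , drop = FALSE]) ==
                   src$labels[te]) else NA_real_
    pred_t <- predict_argmax(B, Xt)
    target_acc[i] <- accuracy(target$labels[eval_mask], pred_t[eval_mask],
                              excluded = excluded)
    if (i == 1L) first_pred <- pred_t
  }
  structure(list(predicted_labels = first_pred, scores = NULL,
                 selected_genes = genes,
                 heldout_accuracy_runs = heldout,
                 target_accuracy_runs = target_acc,
                 heldout_mean = mean(heldout),
                 heldout_sd = if (n_repeats > 1) stats::sd(heldout) else NA_real_,
                 target_mean = mean(target_acc),
                 target_sd = if (n_repeats > 1) stats::sd(target_acc) else NA_real_,
                 majority_vote_accuracy =
                   majority_vote_accuracy(src$labels,
                                          target$labels[eval_mask]),
                 seeds = seeds, mode = "benchmark:top_mean_linear"),
            class = "transfer_result")
}
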