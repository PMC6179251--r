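test_that("a perfectly separating feature gives 100% held-out accuracy", {
  sep <- separable_binned(100)
  fit <- train_model(sep$binned, sep$labels, seed = 1)
  expect_equal(fit$heldout_accuracy, 100)
  # target equal to the training data reproduces the labels
  sm <- predict(fit$model, sep$binned)
  expect_equal(assign_with_threshold(sm, 0), sep$labels)
})

test_that("training is deterministic under a fixed seed", {
  sim <- small_sim(seed = 5)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 40, k_mi = 40)
  f1 <- train_model(eng$source_binned, sim$source$labels, seed = 11)
  f2 <- train_model(eng$source_binned, sim$source$labels, seed = 11)
  expect_identical(predict(f1$model, eng$target_binned)$scores,
                   predict(f2$model, eng$target_binned)$scores)
  f3 <- train_model(eng$source_binned, sim$source$labels, seed = 12)
  expect_false(identical(predict(f1$model, eng$target_binned)$scores,
                         predict(f3$model, eng$target_binned)$scores))
})

test_that("permuted labels give chance-level held-out accuracy", {
  sim <- small_sim(seed = 6)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 40, k_mi = 40)
  share <- 100 * max(table(sim$source$labels)) / length(sim$source$labels)
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    perm <- sample(sim$source$labels)
    train_model(eng$source_binned, perm, seed = s)$heldout_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - share), 10)
})

test_that("multiclass scores are row-normalized probabilities", {
  sim <- small_sim(seed = 8)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 40, k_mi = 40)
  fit <- train_model(eng$source_binned, sim$source$labels, seed = 2)
  sm <- predict(fit$model, eng$target_binned)
  expect_true(all(abs(rowSums(sm$scores) - 1) < 1e-6))
  expect_true(all(sm$scores >= 0 & sm$scores <= 1))
  # single-cell target: one row, still normalized
  one <- binned_matrix(eng$target_binned$codes[1, , drop = FALSE],
                       eng$target_binned$feature_ids)
  expect_equal(sum(predict(fit$model, one)$scores), 1, tolerance = 1e-6)
})

test_that("prediction rejects mismatched feature spaces", {
  sep <- separable_binned(50)
  fit <- train_model(sep$binned, sep$labels, seed = 1)
  wrong <- binned_matrix(sep$binned$codes[, 1:2], c("sep", "noise1"))
  expect_error(predict(fit$model, wrong), "features",
               class = "sctransfer_input_error")
})

test_that("single-class training input is rejected", {
  sep <- separable_binned(20)
  expect_error(train_model(sep$binned, rep("A", nrow(sep$binned$codes))),
               class = "sctransfer_input_error")
})

test_that("model bundles round-trip through disk with bit-identical scores", {
  sim <- small_sim(seed = 9)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 40, k_mi = 40)
  fit <- train_model(eng$source_binned, sim$source$labels, seed = 3,
                     fs = eng$feature_set)
  d <- withr::local_tempdir()
  save_model(fit$model, d)
  back <- load_model(d)
  expect_identical(predict(back, eng$target_binned)$scores,
                   predict(fit$model, eng$target_binned)$scores)
  expect_equal(back$class_order, fit$model$class_order)
  expect_equal(back$feature_set$genes, eng$feature_set$genes)
})

test_that("threshold assignment: argmax, threshold, tie-break", {
  sm <- score_matrix(rbind(c(0.95, 0.10), c(0.70, 0.60), c(0.80, 0.80)))
  colnames(sm$scores) <- c("t1", "t2")
  expect_equal(assign_with_threshold(sm, 0.9)[1], "t1")
  expect_equal(assign_with_threshold(sm, 0.8)[2], "unknown")
  expect_equal(assign_with_threshold(sm, 0.8)[3], "t1")  # tie -> first type
})

test_that("multiclass transfer beats majority vote and matches source-on-source", {
  sim <- small_sim(seed = 10)
  res <- run_multiclass(sim$source, sim$target, n_repeats = 2, base_seed = 1)
  expect_length(res$heldout_accuracy_runs, 2)
  expect_length(res$target_accuracy_runs, 2)
  expect_gt(res$target_mean, res$majority_vote_accuracy)

  # target identical to source: no transfer gap beyond a small margin
  same <- run_multiclass(sim$source, sim$source, n_repeats = 2, base_seed = 1)
  expect_gte(same$target_mean, same$heldout_mean - 5)

  one <- run_multiclass(sim$source, sim$target, n_repeats = 1, base_seed = 1)
  expect_true(is.na(one$target_sd))
})

test_that("fixed seeds reproduce every reported number exactly", {
  sim <- small_sim(seed = 12)
  r1 <- run_multiclass(sim$source, sim$target, n_repeats = 2, base_seed = 4)
  r2 <- run_multiclass(sim$source, sim$target, n_repeats = 2, base_seed = 4)
  expect_identical(r1$target_accuracy_runs, r2$target_accuracy_runs)
  expect_identical(r1$heldout_accuracy_runs, r2$heldout_accuracy_runs)
  expect_identical(r1$predicted_labels, r2$predicted_labels)
})

test_that("excluded-label source cells are dropped from training but targets keep them", {
  sim <- small_sim(seed = 13)
  src <- sim$source
  # relabel some source cells as unusable ground truth
  src$labels[1:10] <- "unknown"
  src$labels[11:15] <- "beta contaminated"
  res <- run_multiclass(src, sim$target, n_repeats = 1, base_seed = 1)
  expect_false(any(c("unknown", "beta contaminated") %in%
                     colnames(res$scores$scores)))
  expect_length(res$predicted_labels, nrow(sim$target$matrix))
})

test_that("per-type mode: thresholds 0 and >1 behave as vacuous and total", {
  sim <- small_sim(seed = 14)
  res0 <- run_per_type(sim$source, sim$target, threshold = 0, base_seed = 1)
  expect_false(any(res0$predicted_labels == "unknown"))
  res1 <- run_per_type(sim$source, sim$target, threshold = 1.01,
                       base_seed = 1)
  expect_true(all(res1$predicted_labels == "unknown"))
  expect_equal(sort(res0$scores$type_ids), sort(unique(sim$source$labels)))
})

test_that("per-type mode skips types with too few positive cells", {
  sim <- small_sim(seed = 15)
  src <- sim$source
  src$labels[src$labels == "type03"] <- "type01"
  src$labels[1] <- "singleton"
  expect_warning(res <- run_per_type(src, sim$target, threshold = 0.8,
                                     base_seed = 1),
                 "singleton")
  expect_true("singleton" %in% res$skipped_types)
  expect_false("singleton" %in% res$scores$type_ids)
})
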