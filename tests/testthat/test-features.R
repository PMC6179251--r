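make_pair <- function(src_genes, tgt_genes, n_cells = 4, seed = 5) {
  set.seed(seed)
  src <- gene_expression_dataset(
    matrix(round(runif(n_cells * length(src_genes), 0, 7), 2), n_cells,
           length(src_genes), dimnames = list(NULL, src_genes)),
    labels = rep(c("a", "b"), length.out = n_cells))
  tgt <- gene_expression_dataset(
    matrix(round(runif(n_cells * length(tgt_genes), 0, 7), 2), n_cells,
           length(tgt_genes), dimnames = list(NULL, tgt_genes)),
    labels = rep(c("a", "b"), length.out = n_cells))
  list(src = src, tgt = tgt)
}

test_that("gene alignment keeps the intersection in source order", {
  p <- make_pair(c("A", "B", "C"), c("B", "C", "D"))
  al <- align_common_genes(p$src, p$tgt)
  expect_equal(al$common_gene_ids, c("B", "C"))
  expect_equal(al$source$gene_ids, al$target$gene_ids)

  p2 <- make_pair(c("A", "B"), c("A", "B"))
  al2 <- align_common_genes(p2$src, p2$tgt)
  expect_equal(al2$source$matrix, p2$src$matrix)
  expect_equal(al2$target$matrix, p2$tgt$matrix)

  p3 <- make_pair(c("A", "B"), c("C", "D"))
  expect_error(align_common_genes(p3$src, p3$tgt), "no shared genes",
               class = "sctransfer_input_error")
})

test_that("rare-gene filter counts expressing cells over the pooled pair", {
  # gene r9: nonzero in 9 pooled cells; gene r10: nonzero in exactly 10
  m_s <- cbind(r9 = c(rep(1, 5), rep(0, 5)), r10 = c(rep(1, 5), rep(0, 5)),
               common = rep(1, 10))
  m_t <- cbind(r9 = c(rep(1, 4), rep(0, 6)), r10 = c(rep(1, 5), rep(0, 5)),
               common = rep(1, 10))
  src <- gene_expression_dataset(m_s, labels = rep("a", 10))
  tgt <- gene_expression_dataset(m_t, labels = rep("a", 10))
  fl <- filter_rare_genes(src, tgt, min_cells = 10)
  expect_equal(fl$source$gene_ids, c("r10", "common"))
  fl0 <- filter_rare_genes(src, tgt, min_cells = 0)
  expect_equal(fl0$source$gene_ids, c("r9", "r10", "common"))
})

test_that("top-mean selection pools cells of both datasets", {
  src <- gene_expression_dataset(cbind(x = c(2, 2), y = c(0, 0)),
                                 labels = c("a", "b"))
  tgt <- gene_expression_dataset(cbind(x = c(4, 4), y = c(1, 1)),
                                 labels = c("a", "b"))
  expect_equal(select_top_mean(src, tgt, k = 1), "x")
  # pooled mean of x is (2+2+4+4)/4 = 3; check through the exhaustive oracle
  expect_equal(oracle_top_mean(src$matrix, tgt$matrix, 2), c("x", "y"))

  single <- make_pair("only", "only")
  expect_equal(select_top_mean(single$src, single$tgt, k = 5), "only")
})

test_that("top-mean selection matches the exhaustive oracle on random data", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:500)
  p <- make_pair(genes, genes, n_cells = 15, seed = 21)
  expect_equal(select_top_mean(p$src, p$tgt, k = 100),
               oracle_top_mean(p$src$matrix, p$tgt$matrix, 100))
})

test_that("ordinal binning respects the half-open interval boundaries", {
  v <- c(0, 0.5, 1, 1.01, 6, 6.01)
  expect_equal(bin_values(v), c(0L, 1L, 1L, 2L, 2L, 3L))
  m <- matrix(v, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  bm <- bin_values(m)
  expect_s3_class(bm, "binned_matrix")
  expect_equal(as.vector(bm$codes), c(0L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(bin_values(rep(0, 5)), rep(0L, 5))
  expect_error(bin_values(c(-0.1, 2)), class = "sctransfer_input_error")
})

test_that("codes are never re-binned: the interval map is not identity on codes", {
  # re-binning {0,1,2,3} with the default edges maps 3 -> 2
  expect_equal(bin_values(c(0, 1, 2, 3)), c(0L, 1L, 2L, 2L))
  bm <- bin_values(matrix(c(0, 2, 7, 1), 2, 2,
                          dimnames = list(NULL, c("a", "b"))))
  expect_error(bin_values(bm), "re-binned", class = "sctransfer_input_error")
})

test_that("binning conserves zeros exactly", {
  set.seed(9)
  m <- matrix(rbinom(200, 1, 0.5) * runif(200, 0, 10), 20, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  bm <- bin_values(m)
  expect_equal(sum(bm$codes == 0), sum(m == 0))
  expect_equal(which(bm$codes == 0), which(m == 0))
})

test_that("mutual information: known values and oracle equivalence", {
  expect_equal(mutual_information(rep(1, 10), rep(c("a", "b"), 5)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1)
  set.seed(4)
  tab <- matrix(sample(0:5, 12, TRUE), 4, 3)
  pr <- table_to_pairs(tab)
  expect_equal(mutual_information(pr$x, pr$y), oracle_mi_from_table(tab),
               tolerance = 1e-13)
  expect_error(mutual_information(1:3, 1:4), class = "sctransfer_input_error")
})

test_that("MI gene ranking matches an exhaustive per-gene oracle", {
  set.seed(31)
  n <- 80
  labels <- sample(c("a", "b", "c"), n, TRUE)
  codes <- matrix(sample(0:3, n * 200, TRUE), n, 200,
                  dimnames = list(NULL, sprintf("g%03d", 1:200)))
  # one gene perfectly tracks the label
  codes[, "g001"] <- match(labels, c("a", "b", "c"))
  bm <- binned_matrix(codes)
  top <- select_top_mi(bm, labels, k = 10)
  expect_equal(top[1], "g001")

  oracle_mi <- vapply(colnames(codes), function(g)
    oracle_mi_from_table(as.matrix(table(codes[, g], labels))), numeric(1))
  ord <- order(-oracle_mi, names(oracle_mi))
  expect_equal(select_top_mi(bm, labels, k = 25),
               names(oracle_mi)[ord][1:25])
  # k larger than gene count returns everything
  expect_length(select_top_mi(bm, labels, k = 1000), 200)
  expect_error(select_top_mi(bm, rep("a", n), k = 5), "one class",
               class = "sctransfer_input_error")
})

test_that("correlation pruning keeps one of a duplicated pair, both of an anticorrelated pair", {
  set.seed(6)
  base <- rnorm(30)
  vals <- cbind(f1 = base, f2 = base, f3 = -base + rnorm(30, sd = 1e-8),
                f4 = rnorm(30))
  pr <- prune_correlated(vals, c("f1", "f2", "f3", "f4"))
  expect_equal(pr$retained, c("f1", "f3", "f4"))
  expect_equal(unname(pr$dropped["f2"]), "correlated_with:f1")
})

test_that("zero-variance features are dropped with a recorded reason", {
  vals <- cbind(flat = rep(2, 10), ok = rnorm(10))
  pr <- prune_correlated(vals, c("flat", "ok"))
  expect_equal(pr$retained, "ok")
  expect_equal(unname(pr$dropped["flat"]), "zero_variance")
})

test_that("pruning soundness on random matrices (exhaustive pairwise check)", {
  set.seed(12)
  for (rep in 1:5) {
    # induce some strongly correlated clusters
    latent <- matrix(rnorm(40 * 5), 40, 5)
    mix <- latent[, sample(5, 30, TRUE)] + matrix(rnorm(40 * 30, sd = 0.1),
                                                  40, 30)
    colnames(mix) <- sprintf("f%02d", 1:30)
    pr <- prune_correlated(mix, colnames(mix), r_max = 0.9)
    cm <- stats::cor(mix)
    for (i in pr$retained) for (j in pr$retained)
      if (i != j) expect_lte(cm[i, j], 0.9)
    for (f in names(pr$dropped)) {
      partner <- sub("correlated_with:", "", pr$dropped[f])
      expect_true(partner %in% pr$retained)
      expect_gt(cm[f, partner], 0.9)
    }
  }
})

test_that("constant-bin removal keeps any column with two distinct codes", {
  codes <- cbind(const3 = rep(3L, 6), mixed = c(0L, 3L, 0L, 3L, 0L, 3L))
  bm <- binned_matrix(codes)
  out <- drop_constant_bins(bm)
  expect_equal(out$feature_ids, "mixed")
  allconst <- binned_matrix(cbind(a = rep(1L, 4)))
  expect_error(drop_constant_bins(allconst),
               class = "sctransfer_degenerate_error")
})

test_that("a gene constant in the source but varying in the target survives the pooled constancy test", {
  src <- gene_expression_dataset(
    cbind(g1 = rep(0, 12), g2 = runif(12, 2, 5), g3 = c(rep(0, 6), rep(7, 6))),
    labels = rep(c("a", "b"), 6))
  tgt <- gene_expression_dataset(
    cbind(g1 = c(rep(0, 6), rep(7, 6)), g2 = runif(12, 2, 5),
          g3 = c(rep(0, 6), rep(7, 6))),
    labels = rep(c("a", "b"), 6))
  eng <- engineer_features(src, tgt, src$labels, k_mean = 3, k_mi = 3,
                           min_cells = 0)
  expect_true("g1" %in% eng$feature_set$genes)
})

test_that("pipeline: union bound, monotone step counts, provenance, determinism", {
  sim <- small_sim(seed = 2)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 50, k_mi = 50)
  lg <- eng$log
  expect_gte(lg$union, 50)
  expect_lte(lg$union, 100)
  expect_lte(lg$after_corr_prune, lg$union)
  expect_lte(lg$after_constant_bin, lg$after_corr_prune)
  expect_true(all(lengths(eng$feature_set$provenance) >= 1))
  expect_false(any(eng$feature_set$genes %in% names(eng$feature_set$dropped)))
  expect_equal(eng$source_binned$feature_ids, eng$feature_set$genes)

  eng2 <- engineer_features(sim$source, sim$target, sim$source$labels,
                            k_mean = 50, k_mi = 50)
  expect_identical(eng, eng2)
})

test_that("identical source and target yield identical binned matrices", {
  sim <- small_sim(seed = 3)
  eng <- engineer_features(sim$source, sim$source, sim$source$labels,
                           k_mean = 30, k_mi = 30)
  expect_identical(eng$source_binned, eng$target_binned)
})

test_that("a k=1 pipeline on a 2-gene dataset still yields a feature", {
  src <- gene_expression_dataset(
    cbind(g1 = c(rep(0, 10), rep(5, 10)), g2 = runif(20, 0, 3)),
    labels = rep(c("a", "b"), each = 10))
  tgt <- gene_expression_dataset(
    cbind(g1 = c(rep(0, 10), rep(5, 10)), g2 = runif(20, 0, 3)),
    labels = rep(c("a", "b"), each = 10))
  eng <- engineer_features(src, tgt, src$labels, k_mean = 1, k_mi = 1,
                           min_cells = 0)
  expect_gte(length(eng$feature_set$genes), 1)
})

test_that("feature sets serialize to JSON and back losslessly", {
  sim <- small_sim(seed = 4)
  eng <- engineer_features(sim$source, sim$target, sim$source$labels,
                           k_mean = 40, k_mi = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_set(eng$feature_set, path)
  back <- read_feature_set(path)
  expect_equal(back$genes, eng$feature_set$genes)
  expect_equal(back$provenance, eng$feature_set$provenance)
  expect_equal(back$bin_edges, eng$feature_set$bin_edges)
  expect_equal(sort(names(back$dropped)),
               sort(names(eng$feature_set$dropped)))
})
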