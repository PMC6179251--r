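# Feature engineering: the univariate pipeline that brings a source and a
# target dataset to a common feature space before classification.
#   1. keep genes present in both datasets
#   2. drop genes expressed in < min_cells pooled cells
#   3. top-k genes by pooled mean expression
#   4. top-k genes by mutual information with the source labels (on binned
#      values)
#   5. union of the two lists (100-200 genes at the default k = 100)
#   6. greedy removal of genes correlated (Pearson r > r_max) with a
#      higher-priority retained gene
#   7. ordinal binning into the fixed bins [0], (0,1], (1,6], (6,Inf)
#   8. removal of genes constant in code space over the pooled cells

#' Restrict two datasets to their shared genes
#'
#' Genes present in only one dataset carry no transferable signal; both
#' datasets are reduced to the intersection of their gene universes, in
#' source order.
#'
#' @param source,target [gene_expression_dataset()] objects.
#' @return List with `source`, `target` (restricted, identically ordered
#'   gene sets) and `common_gene_ids`.
#' @export
align_common_genes <- function(source, target) {
  common <- intersect(source$gene_ids, target$gene_ids)
  if (!length(common))
    stop_input("no shared genes between source and target datasets")
  list(source = ds_subset(source, genes = common),
       target = ds_subset(target, genes = common),
       common_gene_ids = common)
}

#' Remove rarely expressed genes
#'
#' A gene is kept iff it has a non-zero value in at least `min_cells` cells,
#' counted over the pooled cells of both datasets (`pooled = FALSE` requires
#' the bound in each dataset separately). The threshold is strict: "fewer
#' than `min_cells`" cells means removal.
#'
#' @param source,target Datasets with identical, aligned gene sets.
#' @param min_cells Minimum number of expressing cells (default 10).
#' @param pooled Count expressing cells over both datasets together.
#' @return List with filtered `source` and `target`.
#' @export
filter_rare_genes <- function(source, target, min_cells = 10, pooled = TRUE) {
  if (!identical(source$gene_ids, target$gene_ids))
    stop_input("gene sets are not aligned; call align_common_genes() first")
  nz_s <- colSums(source$matrix > 0)
  nz_t <- colSums(target$matrix > 0)
  keep <- if (pooled) (nz_s + nz_t) >= min_cells
          else nz_s >= min_cells & nz_t >= min_cells
  if (!any(keep))
    stop_degenerate("all genes are expressed in fewer than %d cells", min_cells)
  list(source = ds_subset(source, genes = which(keep)),
       target = ds_subset(target, genes = which(keep)))
}

# Pooled per-gene mean: total expression over all cells of both datasets
# divided by the total cell count.
pooled_gene_means <- function(source, target) {
  (colSums(source$matrix) + colSums(target$matrix)) /
    (nrow(source$matrix) + nrow(target$matrix))
}

# Deterministic top-k of a named statistic: statistic descending, gene id
# ascending on ties.
top_k_ids <- function(stat, k) {
  ord <- order(-stat, names(stat), method = "radix")
  names(stat)[ord][seq_len(min(k, length(stat)))]
}

#' Select genes with the highest pooled mean expression
#'
#' @param source,target Aligned datasets.
#' @param k Number of genes to select (all genes if fewer exist).
#' @return Character vector of gene ids, ordered by decreasing pooled mean
#'   (ties broken by gene id).
#' @export
select_top_mean <- function(source, target, k = 100) {
  if (!identical(source$gene_ids, target$gene_ids))
    stop_input("gene sets are not aligned; call align_common_genes() first")
  if (k < 1) stop_input("k must be >= 1")
  top_k_ids(pooled_gene_means(source, target), k)
}

#' Bin expression values into four ordinal codes
#'
#' Maps continuous values to the fixed ordinal bins `[0]`, `(0, 1]`,
#' `(1, 6]`, `(6, Inf)` (codes 0-3). On the default edges a code of 0 means
#' the underlying value was exactly zero. Codes must never be re-binned:
#' re-applying the map to codes is not the identity (3 would fall into bin
#' 2), so passing an already binned matrix is an error.
#'
#' @param x Non-negative numeric matrix (cells x features) or vector.
#' @param edges Three increasing thresholds `(e1, e2, e3)`; codes are
#'   `0: x <= e1`, `1: e1 < x <= e2`, `2: e2 < x <= e3`, `3: x > e3`.
#' @return For matrix input, a `binned_matrix` (fields `codes`,
#'   `feature_ids`, `edges`); for vector input, an integer vector of codes.
#' @export
bin_values <- function(x, edges = c(0, 1, 6)) {
  if (inherits(x, "binned_matrix"))
    stop_input("input is already binned; ordinal codes must not be re-binned")
  if (length(edges) != 3 || is.unsorted(edges, strictly = TRUE))
    stop_input("edges must be three strictly increasing thresholds")
  vals <- if (is.matrix(x)) x else as.numeric(x)
  if (any(vals < 0)) stop_input("cannot bin negative expression values")
  codes <- (vals > edges[1]) + (vals > edges[2]) + (vals > edges[3])
  if (!is.matrix(x)) return(as.integer(codes))
  storage.mode(codes) <- "integer"
  dimnames(codes) <- dimnames(x)
  binned_matrix(codes, colnames(x), edges)
}

#' Construct a binned (ordinal code) matrix
#'
#' @param codes Integer cells x features matrix with values in `{0,1,2,3}`.
#' @param feature_ids Feature (gene) identifiers, one per column.
#' @param edges The bin edges the codes were derived with.
#' @return Object of class `binned_matrix`.
#' @export
binned_matrix <- function(codes, feature_ids = colnames(codes),
                          edges = c(0, 1, 6)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(codes)))
  if (length(feature_ids) != ncol(codes))
    stop_input("feature_ids length does not match number of columns")
  if (length(codes) && (min(codes) < 0L || max(codes) > 3L))
    stop_input("bin codes must lie in {0,1,2,3}")
  colnames(codes) <- feature_ids
  structure(list(codes = codes, feature_ids = as.character(feature_ids),
                 edges = as.numeric(edges)),
            class = "binned_matrix")
}

#' @exportS3Method base::print
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d cells x %d features, edges (%s)\n",
              nrow(x$codes), ncol(x$codes),
              paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$codes)

#' Mutual information between two nominal variables
#'
#' Plug-in estimate, in bits: `I(X;Y) = sum p(x,y) log2(p(x,y)/(p(x)p(y)))`
#' over the empirical joint distribution, with zero-probability cells
#' contributing zero. Used to rank binned genes by how informative they are
#' about the cell-type label.
#'
#' @param x,y Equal-length vectors of nominal values (e.g. bin codes and
#'   class labels).
#' @return Mutual information in bits, >= 0.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop_input("mutual information inputs differ in length (%d vs %d)",
               length(x), length(y))
  if (length(x) < 2) stop_input("need at least two observations")
  joint <- table(x, y)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p)
  py <- colSums(p)
  expect <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / expect[nz]))
}

# Mutual information of every column of a code matrix with a label vector,
# vectorized over genes: for each (code value, class) pair the per-gene joint
# counts are a single colSums over the cells of that class.
mi_per_gene <- function(codes, labels) {
  labels <- as.character(labels)
  n <- nrow(codes)
  classes <- sort(unique(labels))
  code_vals <- 0:3
  joint <- array(0, dim = c(length(code_vals), length(classes), ncol(codes)))
  for (ci in seq_along(classes)) {
    sub <- codes[labels == classes[ci], , drop = FALSE]
    for (vi in seq_along(code_vals))
      joint[vi, ci, ] <- colSums(sub == code_vals[vi])
  }
  p <- joint / n
  py <- colSums(matrix(p[, , 1], nrow = length(code_vals)))  # class marginals
  mi <- numeric(ncol(codes))
  for (j in seq_len(ncol(codes))) {
    pj <- p[, , j]
    px <- rowSums(pj)
    expect <- outer(px, py)
    nz <- pj > 0
    mi[j] <- sum(pj[nz] * log2(pj[nz] / expect[nz]))
  }
  names(mi) <- colnames(codes)
  mi
}

#' Select genes most informative about the source labels
#'
#' Ranks binned genes by plug-in mutual information with the class label,
#' computed on the source dataset only, and returns the top `k` (ties broken
#' by gene id).
#'
#' @param source_codes A [binned_matrix()] of the source dataset.
#' @param labels Per-cell class labels (>= 2 distinct values).
#' @param k Number of genes to select.
#' @return Character vector of gene ids ordered by decreasing mutual
#'   information.
#' @export
select_top_mi <- function(source_codes, labels, k = 100) {
  labels <- as.character(labels)
  if (length(labels) != nrow(source_codes$codes))
    stop_input("labels length (%d) does not match cell count (%d)",
               length(labels), nrow(source_codes$codes))
  if (length(unique(labels)) < 2)
    stop_input("mutual information undefined for one class")
  top_k_ids(mi_per_gene(source_codes$codes, labels), k)
}

#' Greedily remove correlated features
#'
#' Scans features in priority order and drops each feature whose Pearson
#' correlation with an already retained feature exceeds `r_max` (strictly).
#' Correlation is computed on continuous values, normally the pooled cells
#' of both datasets. By default the threshold applies to signed r (strongly
#' anticorrelated pairs are both kept); `abs_corr = TRUE` thresholds `|r|`.
#' Zero-variance features have undefined correlation and are dropped with
#' reason `"zero_variance"` (they would be removed as constant-bin features
#' later in any case).
#'
#' @param values Numeric cells x features matrix with feature ids as column
#'   names.
#' @param feature_order Feature ids in decreasing priority; the first
#'   feature of a correlated pair encountered in this order is the one kept.
#' @param r_max Correlation threshold (default 0.9, strict).
#' @param abs_corr Threshold on `|r|` instead of signed r.
#' @return List with `retained` (ids, in priority order) and `dropped`
#'   (named character vector, feature -> reason, reasons
#'   `"correlated_with:<id>"` or `"zero_variance"`).
#' @export
prune_correlated <- function(values, feature_order = colnames(values),
                             r_max = 0.9, abs_corr = FALSE) {
  if (!length(feature_order)) stop_input("no features to prune")
  if (!all(feature_order %in% colnames(values)))
    stop_input("feature_order contains ids absent from the value matrix")
  values <- values[, feature_order, drop = FALSE]
  sds <- apply(values, 2, stats::sd)
  zerovar <- feature_order[sds == 0]
  live <- setdiff(feature_order, zerovar)
  dropped <- stats::setNames(rep("zero_variance", length(zerovar)), zerovar)
  if (length(live) > 1) {
    cm <- stats::cor(values[, live, drop = FALSE])
  } else {
    cm <- matrix(1, length(live), length(live), dimnames = list(live, live))
  }
  if (abs_corr) cm <- abs(cm)
  retained <- character(0)
  for (f in live) {
    if (length(retained)) {
      r <- cm[f, retained]
      hit <- r > r_max
      if (any(hit)) {
        partner <- retained[which.max(r)]
        dropped[f] <- paste0("correlated_with:", partner)
        next
      }
    }
    retained <- c(retained, f)
  }
  list(retained = retained, dropped = dropped)
}

#' Remove features that are constant in code space
#'
#' Features whose ordinal code is identical in every cell carry no
#' information for a tree split and are removed. In the full pipeline
#' constancy is judged on the pooled cells of both datasets, so a gene
#' constant in the source but varying in the target survives.
#'
#' @param binned A [binned_matrix()]; in the pipeline, the row-bound pooled
#'   source + target codes.
#' @return The matrix without constant columns.
#' @export
drop_constant_bins <- function(binned) {
  if (!ncol(binned$codes)) stop_input("empty binned matrix")
  keep <- constant_bin_columns(binned$codes)
  if (!any(keep))
    stop_degenerate("no informative features: all features fall in a single bin")
  binned_matrix(binned$codes[, keep, drop = FALSE],
                binned$feature_ids[keep], binned$edges)
}

# TRUE for columns worth keeping (non-constant).
constant_bin_columns <- function(codes) {
  apply(codes, 2, function(col) length(unique(col)) > 1L)
}

#' Feature set descriptor
#'
#' The ordered list of genes surviving the feature-engineering pipeline,
#' with per-gene provenance (selected by pooled mean, by mutual information,
#' or both), the ordinal bin edges, the genes dropped late in the pipeline
#' with the reason, and the pipeline parameters.
#'
#' @param genes Ordered retained gene ids.
#' @param provenance Named list, gene -> character vector of tags from
#'   `{"mean_selected", "mi_selected"}`.
#' @param bin_edges Ordinal bin thresholds.
#' @param dropped Named character vector, gene -> reason.
#' @param params Named list of pipeline parameters.
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(genes, provenance, bin_edges = c(0, 1, 6),
                        dropped = character(0), params = list()) {
  genes <- as.character(genes)
  if (!length(genes)) stop_degenerate("feature set is empty")
  if (any(genes %in% names(dropped)))
    stop_input("a gene cannot be both retained and dropped")
  if (!all(genes %in% names(provenance)))
    stop_input("every retained gene needs a provenance tag")
  structure(list(genes = genes, provenance = provenance[genes],
                 bin_edges = as.numeric(bin_edges),
                 dropped = dropped, params = params),
            class = "feature_set")
}

#' @exportS3Method base::print
print.feature_set <- function(x, ...) {
  tags <- vapply(x$provenance, paste, "", collapse = "+")
  cat(sprintf("feature_set: %d genes (%d mean-selected, %d MI-selected), %d dropped, edges (%s)\n",
              length(x$genes), sum(grepl("mean_selected", tags)),
              sum(grepl("mi_selected", tags)), length(x$dropped),
              paste(x$bin_edges, collapse = ", ")))
  invisible(x)
}

#' Serialize a feature set to JSON
#'
#' @param fs A [feature_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_set <- function(fs, path) {
  jsonlite::write_json(list(genes = fs$genes, provenance = fs$provenance,
                            bin_edges = fs$bin_edges,
                            dropped = as.list(fs$dropped),
                            params = fs$params),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature set from JSON
#'
#' @param path File written by [write_feature_set()].
#' @return A [feature_set()].
#' @export
read_feature_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- x$provenance
  if (is.data.frame(prov)) prov <- as.list(prov)
  prov <- lapply(prov, as.character)
  dropped <- unlist(x$dropped)
  if (is.null(dropped))
    dropped <- stats::setNames(character(0), character(0))
  feature_set(x$genes, prov, x$bin_edges, dropped, as.list(x$params))
}

#' Run the full feature-engineering pipeline
#'
#' Composes gene alignment, rare-gene removal, pooled-mean and
#' mutual-information selection, the union of the two gene lists,
#' correlation pruning, ordinal binning and constant-bin removal, producing
#' a common binned feature space for source and target. The per-step feature
#' counts are returned in `$log`.
#'
#' For correlation pruning the priority order is: MI-selected genes by
#' decreasing mutual information, then mean-only genes by decreasing pooled
#' mean, so the retained member of a correlated pair is always the more
#' label-informative one.
#'
#' @param source,target [gene_expression_dataset()] objects on log2 scale.
#' @param labels Source per-cell labels (defaults to `source$labels`); a
#'   binary 0/1 indicator in per-type mode.
#' @param k_mean,k_mi Number of genes for the mean and mutual-information
#'   selections (default 100 each).
#' @param r_max Correlation-pruning threshold (default 0.9).
#' @param min_cells Rare-gene threshold (default 10 pooled expressing cells).
#' @param edges Ordinal bin thresholds (default `c(0, 1, 6)`).
#' @param abs_corr Prune on `|r|` instead of signed r.
#' @param corr_on Compute pruning correlations on `"pooled"` cells (default)
#'   or the `"source"` only.
#' @return List with `feature_set`, `source_binned`, `target_binned`, `log`.
#' @export
engineer_features <- function(source, target, labels = source$labels,
                              k_mean = 100, k_mi = k_mean, r_max = 0.9,
                              min_cells = 10, edges = c(0, 1, 6),
                              abs_corr = FALSE,
                              corr_on = c("pooled", "source")) {
  corr_on <- match.arg(corr_on)
  labels <- as.character(labels)
  if (length(labels) != nrow(source$matrix))
    stop_input("labels length (%d) does not match source cell count (%d)",
               length(labels), nrow(source$matrix))
  log <- list()

  al <- align_common_genes(source, target)
  log$after_align <- length(al$common_gene_ids)

  fl <- filter_rare_genes(al$source, al$target, min_cells = min_cells)
  log$after_rare_filter <- ncol(fl$source$matrix)

  means <- pooled_gene_means(fl$source, fl$target)
  mean_ids <- top_k_ids(means, k_mean)

  src_codes_all <- bin_values(fl$source$matrix, edges)
  mis <- mi_per_gene(src_codes_all$codes, labels)
  if (length(unique(labels)) < 2)
    stop_input("mutual information undefined for one class")
  mi_ids <- top_k_ids(mis, k_mi)

  union_ids <- union(mi_ids, setdiff(mean_ids, mi_ids))
  log$mean_selected <- length(mean_ids)
  log$mi_selected <- length(mi_ids)
  log$union <- length(union_ids)

  # priority: MI-selected by MI desc, then mean-only by mean desc
  priority <- c(mi_ids, setdiff(mean_ids, mi_ids))
  pool_vals <- if (corr_on == "pooled") {
    rbind(fl$source$matrix[, priority, drop = FALSE],
          fl$target$matrix[, priority, drop = FALSE])
  } else {
    fl$source$matrix[, priority, drop = FALSE]
  }
  pr <- prune_correlated(pool_vals, priority, r_max = r_max,
                         abs_corr = abs_corr)
  log$after_corr_prune <- length(pr$retained)

  sb <- bin_values(fl$source$matrix[, pr$retained, drop = FALSE], edges)
  tb <- bin_values(fl$target$matrix[, pr$retained, drop = FALSE], edges)
  keep <- constant_bin_columns(rbind(sb$codes, tb$codes))
  if (!any(keep))
    stop_degenerate("no informative features: all features fall in a single bin")
  dropped <- pr$dropped
  const_ids <- pr$retained[!keep]
  dropped[const_ids] <- "constant_bin"
  retained <- pr$retained[keep]
  log$after_constant_bin <- length(retained)

  prov <- lapply(retained, function(g)
    c(if (g %in% mi_ids) "mi_selected", if (g %in% mean_ids) "mean_selected"))
  names(prov) <- retained

  fs <- feature_set(retained, prov, edges, dropped,
                    params = list(k_mean = k_mean, k_mi = k_mi, r_max = r_max,
                                  min_cells = min_cells, abs_corr = abs_corr,
                                  corr_on = corr_on))
  list(feature_set = fs,
       source_binned = binned_matrix(sb$codes[, retained, drop = FALSE],
                                     retained, edges),
       target_binned = binned_matrix(tb$codes[, retained, drop = FALSE],
                                     retained, edges),
       log = log)
}
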