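# Small in-code fixtures shared across test files.

# A tiny deterministic dataset: n_cells x n_genes values on log2 scale.
tiny_dataset <- function(n_cells = 6, n_genes = 4, labels = NULL, seed = 42,
                         gene_ids = sprintf("g%02d", seq_len(n_genes)),
                         cell_prefix = "c") {
  set.seed(seed)
  m <- matrix(round(runif(n_cells * n_genes, 0, 8), 3), n_cells, n_genes,
              dimnames = list(paste0(cell_prefix, seq_len(n_cells)),
                              gene_ids))
  if (is.null(labels))
    labels <- rep(c("alpha", "beta"), length.out = n_cells)
  gene_expression_dataset(m, labels = labels)
}

# A small, quick source/target simulation for classifier-level tests:
# 3 types, 60 cells/type source, light batch shift.
small_sim <- function(seed = 7, ...) {
  simulate_pair(simulation_config(
    n_genes = 400, n_types = 3, n_markers_per_type = 12,
    cells_per_type_source = 60, cells_per_type_target = c(50, 40, 30),
    dropout_source = 0.2, dropout_target = 0.3, depth_factor_target = 1.5,
    gene_overlap_frac = 0.95, seed = seed, ...))
}

# Perfectly separable binned data: one feature that encodes the class.
separable_binned <- function(n_per_class = 100, seed = 3) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n_per_class)
  codes <- cbind(sep = ifelse(y == "A", 0L, 3L),
                 noise1 = sample(0:3, 2 * n_per_class, TRUE),
                 noise2 = sample(0:3, 2 * n_per_class, TRUE))
  rownames(codes) <- paste0("c", seq_len(nrow(codes)))
  list(binned = binned_matrix(codes), labels = y)
}
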