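#' Construct a labeled gene-expression dataset
#'
#' The basic container: a dense cells x genes matrix of non-negative
#' expression values (usually log2(count + 1)), with unique gene identifiers,
#' unique cell identifiers, and one label per cell.
#'
#' @param matrix Numeric cells x genes matrix, values >= 0 and finite.
#' @param gene_ids Character vector, one unique id per column.
#' @param cell_ids Character vector, one unique id per row.
#' @param labels Character vector, one label per cell. Labels such as
#'   "unknown" or "contaminated" are legal; see [is_excluded_label()].
#' @return An object of class `gene_expression_dataset` with fields
#'   `matrix`, `gene_ids`, `cell_ids`, `labels`.
#' @export
gene_expression_dataset <- function(matrix, gene_ids = colnames(matrix),
                                    cell_ids = rownames(matrix), labels) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(matrix)))
  if (is.null(cell_ids)) cell_ids <- paste0("C", seq_len(nrow(matrix)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  if (length(gene_ids) != ncol(matrix))
    stop_input("gene_ids length (%d) does not match number of genes (%d)",
               length(gene_ids), ncol(matrix))
  if (length(cell_ids) != nrow(matrix))
    stop_input("cell_ids length (%d) does not match number of cells (%d)",
               length(cell_ids), nrow(matrix))
  if (length(labels) != nrow(matrix))
    stop_input("labels length (%d) does not match number of cells (%d): check that the labels file matches the matrix",
               length(labels), nrow(matrix))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop_input("duplicate gene identifiers: %s",
               paste(utils::head(dup, 10), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop_input("duplicate cell identifiers")
  if (any(!is.finite(matrix)))
    stop_input("expression matrix contains non-finite values")
  if (any(matrix < 0))
    stop_input("expression matrix contains negative values; expected raw counts or log2(x+1) values")
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels),
            class = "gene_expression_dataset")
}

#' @exportS3Method base::print
print.gene_expression_dataset <- function(x, ...) {
  cat(sprintf("gene_expression_dataset: %d cells x %d genes, %d label classes\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.gene_expression_dataset <- function(x) dim(x$matrix)

# Subset cells and/or genes, keeping all fields aligned.
ds_subset <- function(ds, cells = NULL, genes = NULL) {
  m <- ds$matrix
  lab <- ds$labels
  if (!is.null(cells)) {
    m <- m[cells, , drop = FALSE]
    lab <- lab[if (is.logical(cells)) which(cells) else cells]
  }
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  gene_expression_dataset(m, colnames(m), rownames(m), lab)
}

read_labels_file <- function(labels_path) {
  if (!file.exists(labels_path))
    stop_input("labels file not found: %s", labels_path)
  first <- readLines(labels_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(labels_path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2)
    stop_input("labels file %s must have two columns (cell_id, label)",
               labels_path)
  if (tolower(tab[1, 1]) %in% c("cell_id", "cell", "barcode") ||
      tolower(tab[1, 2]) == "label")
    tab <- tab[-1, , drop = FALSE]
  data.frame(cell_id = as.character(tab[[1]]), label = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}

read_matrix_file <- function(matrix_path, format) {
  if (!file.exists(matrix_path))
    stop_input("matrix file not found: %s", matrix_path)
  if (format == "mtx") {
    dir <- dirname(matrix_path)
    genes_path <- file.path(dir, "genes.tsv")
    cells_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_path) || !file.exists(cells_path))
      stop_input("MTX input requires genes.tsv and barcodes.tsv next to %s",
                 matrix_path)
    m <- as.matrix(Matrix::readMM(matrix_path))
    rn <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    cn <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)[[1]]
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_input("MTX sidecar lengths (%d genes, %d cells) do not match matrix %d x %d",
                 length(rn), length(cn), nrow(m), ncol(m))
    dimnames(m) <- list(rn, cn)
    m
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE,
                            comment.char = "", quote = "\"")
    as.matrix(df)
  }
}

#' Read a labeled expression dataset from disk
#'
#' Reads a delimited (CSV/TSV, first row and column are identifiers) or
#' MatrixMarket matrix (with `genes.tsv` / `barcodes.tsv` sidecars in the
#' same directory) plus a two-column `(cell_id, label)` labels file, and
#' returns the dataset in cells x genes orientation regardless of the
#' on-disk layout. Gzip-compressed delimited files are read transparently.
#'
#' @param matrix_path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @param labels_path Path to the labels file.
#' @param orientation On-disk layout: `"cells_as_rows"` or `"genes_as_rows"`.
#'   MatrixMarket files conventionally store genes as rows.
#' @return A [gene_expression_dataset()].
#' @export
read_dataset <- function(matrix_path, format = c("csv", "tsv", "mtx"),
                         labels_path,
                         orientation = c("cells_as_rows", "genes_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  m <- read_matrix_file(matrix_path, format)
  if (orientation == "genes_as_rows") m <- t(m)
  lab <- read_labels_file(labels_path)
  if (nrow(lab) != nrow(m))
    stop_input("labels file has %d entries but matrix has %d cells",
               nrow(lab), nrow(m))
  cell_ids <- rownames(m) %||% lab$cell_id
  if (!is.null(rownames(m)) && all(lab$cell_id %in% cell_ids)) {
    lab <- lab[match(cell_ids, lab$cell_id), , drop = FALSE]
  }
  gene_expression_dataset(m, colnames(m), cell_ids, lab$label)
}

#' Write a labeled expression dataset to disk
#'
#' Inverse of [read_dataset()]: writes the matrix in the requested format and
#' orientation plus a two-column labels file.
#'
#' @inheritParams read_dataset
#' @param ds A [gene_expression_dataset()].
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, matrix_path, format = c("csv", "tsv", "mtx"),
                          labels_path,
                          orientation = c("cells_as_rows", "genes_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  m <- ds$matrix
  if (orientation == "genes_as_rows") m <- t(m)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), matrix_path)
    dir <- dirname(matrix_path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       matrix_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  utils::write.table(data.frame(cell_id = ds$cell_ids, label = ds$labels),
                     labels_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Ensure a dataset is on log2 scale
#'
#' Applies `x = log2(x + 1)` if the matrix looks like raw counts, and leaves
#' it untouched if it already looks log-scaled. The heuristic is
#' deterministic: a maximum value above `raw_threshold` (default 50) marks
#' the matrix as raw, since log2 of any realistic count + 1 stays well below
#' that. `force = TRUE` applies the transform regardless. The decision is
#' recorded in the `"scale_report"` attribute of the returned dataset.
#'
#' @param ds A [gene_expression_dataset()].
#' @param force Apply the transform unconditionally.
#' @param raw_threshold Maximum value above which the matrix is judged raw.
#' @return The dataset, converted if needed, with attribute `"scale_report"`.
#' @export
to_log_scale <- function(ds, force = FALSE, raw_threshold = 50) {
  mx <- max(ds$matrix)
  if (force || mx > raw_threshold) {
    out <- gene_expression_dataset(log2(ds$matrix + 1), ds$gene_ids,
                                   ds$cell_ids, ds$labels)
    attr(out, "scale_report") <-
      sprintf("converted to log2(x+1)%s (max value %.3g)",
              if (force && mx <= raw_threshold) " [forced]" else "", mx)
  } else {
    out <- ds
    attr(out, "scale_report") <-
      sprintf("already log-scale (max value %.3g <= %g), left unchanged",
              mx, raw_threshold)
  }
  out
}

#' Imbalance ratio of a class-count vector
#'
#' Majority-class count divided by minority-class count, over classes with at
#' least one cell.
#'
#' @param class_counts Named or unnamed vector of per-class cell counts.
#' @return A single number >= 1.
#' @export
imbalance_ratio <- function(class_counts) {
  class_counts <- class_counts[class_counts > 0]
  if (!length(class_counts)) stop_input("no class has a positive count")
  max(class_counts) / min(class_counts)
}

#' Summarize a dataset
#'
#' Descriptive statistics computed on the matrix as loaded, before any gene
#' filtering or feature selection: cell and gene counts, per-class counts,
#' imbalance ratio (majority/minority) and sparsity (percentage of zero
#' values).
#'
#' @param ds A [gene_expression_dataset()].
#' @return An object of class `dataset_summary` with fields `n_cells`,
#'   `n_genes`, `class_counts`, `imbalance_ratio`, `sparsity_pct`.
#' @export
summarize_dataset <- function(ds) {
  if (!nrow(ds$matrix) || !ncol(ds$matrix))
    stop_input("cannot summarize an empty dataset")
  counts <- table(ds$labels)
  cc <- as.integer(counts)
  names(cc) <- names(counts)
  structure(list(n_cells = nrow(ds$matrix), n_genes = ncol(ds$matrix),
                 class_counts = cc,
                 imbalance_ratio = imbalance_ratio(cc),
                 sparsity_pct = 100 * mean(ds$matrix == 0)),
            class = "dataset_summary")
}

#' @exportS3Method base::print
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d cells x %d genes | imbalance %.1f | sparsity %.1f%%\n",
              x$n_cells, x$n_genes, x$imbalance_ratio, x$sparsity_pct))
  cat("classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                x$class_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Cosine similarity between two class-count distributions
#'
#' `dot(a, b) / (|a| |b|)` between two aligned vectors of per-class cell
#' counts; 1 means identical class proportions, 0 means the classes present
#' do not overlap. Used to quantify how differently two datasets sample the
#' same cell types.
#'
#' @param counts_a,counts_b Non-negative count vectors of equal length,
#'   classes aligned in the same order.
#' @return Similarity in \[0, 1\].
#' @export
class_distribution_cosine <- function(counts_a, counts_b) {
  counts_a <- as.numeric(counts_a)
  counts_b <- as.numeric(counts_b)
  if (length(counts_a) != length(counts_b))
    stop_input("count vectors differ in length (%d vs %d)",
               length(counts_a), length(counts_b))
  if (!length(counts_a)) stop_input("empty count vectors")
  if (any(counts_a < 0) || any(counts_b < 0))
    stop_input("counts must be non-negative")
  na <- sqrt(sum(counts_a^2))
  nb <- sqrt(sum(counts_b^2))
  if (na == 0 || nb == 0)
    stop_input("cosine similarity undefined for a zero count vector")
  sum(counts_a * counts_b) / (na * nb)
}
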