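# Synthetic source/target pair generator. The generative model is the
# simplest one exhibiting the three technical axes that separate real
# source/target dataset pairs: library-depth scaling, differing dropout
# rates, and partially non-overlapping gene universes.
#
# Per gene g a baseline log2 intensity mu_g ~ N(baseline_log_mean,
# baseline_log_sd) is drawn once and shared by both datasets; marker genes
# instead draw their baseline from a low-expression regime
# N(marker_off_log_mean, baseline_log_sd), since a usable marker is
# near-silent outside the type it marks. A cell of type t expresses gene g
# at raw intensity 2^(mu_g + marker_effect * [g is a marker of t] + eps),
# eps ~ N(0, noise_log_sd). Target raw values are
# multiplied by depth_factor_target, then each value is independently zeroed
# with the dataset's dropout probability (dropout is applied after depth
# scaling: deeper sequencing reduces technical zeros). Both matrices are
# then mapped to log2(x + 1).

#' Simulation configuration
#'
#' Parameters of the paired source/target simulator. Marker gene sets are
#' disjoint across types and drawn from the genes shared by both datasets,
#' so markers stay usable after gene-universe alignment. Novel types appear
#' only in the target and receive their own marker sets — their cells are
#' the ground truth for unknown-type detection.
#'
#' @param n_genes Genes per dataset.
#' @param n_types Cell types present in the source.
#' @param n_markers_per_type Marker genes per type (disjoint across types).
#' @param cells_per_type_source,cells_per_type_target Integer vectors of
#'   cells per type (length `n_types`, recycled from a scalar).
#' @param marker_effect Log2-units upward shift of a type's markers in its
#'   own cells.
#' @param baseline_log_mean,baseline_log_sd Location/scale of the per-gene
#'   baseline log2 intensity.
#' @param marker_off_log_mean Baseline log2 intensity location of marker
#'   genes outside the type they mark; low by default, since a usable
#'   marker is near-silent in other types.
#' @param noise_log_sd Per-cell log2-scale biological/technical noise sd.
#' @param dropout_source,dropout_target Probability that an observed value
#'   is zeroed.
#' @param depth_factor_target Multiplicative raw-intensity scale of the
#'   target (sequencing-depth ratio).
#' @param gene_overlap_frac Fraction of each dataset's genes shared with the
#'   other.
#' @param novel_types_target Number of extra types present only in the
#'   target.
#' @param novel_cells_per_type Cells per novel target type.
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_types = 5,
                              n_markers_per_type = 20,
                              cells_per_type_source = 300,
                              cells_per_type_target = c(400, 200, 150, 100, 50),
                              marker_effect = 3,
                              baseline_log_mean = 0.5, baseline_log_sd = 1,
                              marker_off_log_mean = -2,
                              noise_log_sd = 1,
                              dropout_source = 0.3, dropout_target = 0.5,
                              depth_factor_target = 2,
                              gene_overlap_frac = 0.9,
                              novel_types_target = 0,
                              novel_cells_per_type = 100,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_types = as.integer(n_types),
              n_markers_per_type = as.integer(n_markers_per_type),
              cells_per_type_source = as.integer(
                if (length(cells_per_type_source) == 1)
                  rep(cells_per_type_source, n_types)
                else cells_per_type_source),
              cells_per_type_target = as.integer(
                if (length(cells_per_type_target) == 1)
                  rep(cells_per_type_target, n_types)
                else cells_per_type_target),
              marker_effect = as.numeric(marker_effect),
              baseline_log_mean = as.numeric(baseline_log_mean),
              baseline_log_sd = as.numeric(baseline_log_sd),
              marker_off_log_mean = as.numeric(marker_off_log_mean),
              noise_log_sd = as.numeric(noise_log_sd),
              dropout_source = as.numeric(dropout_source),
              dropout_target = as.numeric(dropout_target),
              depth_factor_target = as.numeric(depth_factor_target),
              gene_overlap_frac = as.numeric(gene_overlap_frac),
              novel_types_target = as.integer(novel_types_target),
              novel_cells_per_type = as.integer(novel_cells_per_type),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1 || n_types < 1 || n_markers_per_type < 0)
      stop_input("n_genes, n_types must be >= 1 and n_markers_per_type >= 0")
    if (length(cells_per_type_source) != n_types ||
        length(cells_per_type_target) != n_types)
      stop_input("cells_per_type vectors must have length n_types (%d)",
                 n_types)
    if (marker_effect < 0) stop_input("marker_effect must be >= 0")
    if (dropout_source < 0 || dropout_source >= 1 ||
        dropout_target < 0 || dropout_target >= 1)
      stop_input("dropout probabilities must lie in [0, 1)")
    if (depth_factor_target <= 0)
      stop_input("depth_factor_target must be > 0")
    if (gene_overlap_frac <= 0 || gene_overlap_frac > 1)
      stop_input("gene_overlap_frac must lie in (0, 1]")
    total_marked <- (n_types + novel_types_target) * n_markers_per_type
    if (total_marked > round(gene_overlap_frac * n_genes))
      stop_input("not enough shared genes (%d) for %d disjoint marker genes",
                 round(gene_overlap_frac * n_genes), total_marked)
  })
  invisible(cfg)
}

#' Write / read a simulation configuration as JSON
#'
#' @param config A [simulation_config()].
#' @param path JSON file path.
#' @return `write_simulation_config` invisibly returns `path`;
#'   `read_simulation_config` returns the configuration (lossless
#'   round-trip).
#' @export
write_simulation_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_config, x)
}

#' The standard synthetic fixture
#'
#' The default study conditions used throughout the test suite: 5 cell
#' types, 2000 genes, 20 markers per type with a 3 log2-unit effect,
#' dropout 0.3 (source) / 0.5 (target), a 2x target depth factor, 90% gene
#' overlap, 300 source cells per type and an imbalanced target
#' (400/200/150/100/50 cells).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
standard_fixture_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, ...)
}

sim_matrix <- function(mu, type_of_cell, markers, effect, noise_sd,
                       depth_factor, dropout, gene_ids, cell_prefix) {
  n_cells <- length(type_of_cell)
  n_genes <- length(gene_ids)
  shift <- matrix(0, n_cells, n_genes, dimnames = list(NULL, gene_ids))
  for (ty in names(markers)) {
    g <- intersect(markers[[ty]], gene_ids)
    if (length(g)) shift[type_of_cell == ty, g] <- effect
  }
  logval <- matrix(rep(mu[gene_ids], each = n_cells), n_cells, n_genes) +
    shift + matrix(stats::rnorm(n_cells * n_genes, 0, noise_sd),
                   n_cells, n_genes)
  raw <- depth_factor * 2^logval
  if (dropout > 0)
    raw[matrix(stats::runif(n_cells * n_genes) < dropout,
               n_cells, n_genes)] <- 0
  m <- log2(raw + 1)
  dimnames(m) <- list(sprintf("%s%05d", cell_prefix, seq_len(n_cells)),
                      gene_ids)
  m
}

#' Simulate a paired source/target dataset
#'
#' Generates two labeled log2-scale expression datasets from the generative
#' model described in the package vignette: shared per-gene baselines,
#' type-specific marker shifts, and target-side depth scaling, differing
#' dropout, and a partially non-overlapping gene universe. All randomness
#' derives from `config$seed`, so identical configurations reproduce
#' identical datasets.
#'
#' @param config A [simulation_config()].
#' @return List with `source`, `target` ([gene_expression_dataset()]
#'   objects) and `truth` (the marker map `type -> gene ids`, plus the
#'   config).
#' @export
simulate_pair <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(config$seed)
  n_shared <- round(config$gene_overlap_frac * config$n_genes)
  n_priv <- config$n_genes - n_shared
  n_pool <- n_shared + 2 * n_priv
  pool <- sprintf("G%05d", seq_len(n_pool))
  shared <- pool[seq_len(n_shared)]
  src_genes <- c(shared, pool[n_shared + seq_len(n_priv)])
  tgt_genes <- c(shared, pool[n_shared + n_priv + seq_len(n_priv)])

  mu <- stats::setNames(stats::rnorm(n_pool, config$baseline_log_mean,
                                     config$baseline_log_sd), pool)

  known_types <- sprintf("type%02d", seq_len(config$n_types))
  novel_types <- if (config$novel_types_target > 0)
    sprintf("novel%02d", seq_len(config$novel_types_target)) else character(0)
  all_types <- c(known_types, novel_types)
  n_marked <- length(all_types) * config$n_markers_per_type
  marker_pool <- sample(shared, n_marked)
  mu[marker_pool] <- stats::rnorm(n_marked, config$marker_off_log_mean,
                                  config$baseline_log_sd)
  markers <- split(marker_pool,
                   rep(all_types, each = config$n_markers_per_type))
  markers <- markers[all_types]

  src_types <- rep(known_types, times = config$cells_per_type_source)
  tgt_types <- c(rep(known_types, times = config$cells_per_type_target),
                 rep(novel_types, each = config$novel_cells_per_type))

  sm <- sim_matrix(mu, src_types, markers, config$marker_effect,
                   config$noise_log_sd, 1, config$dropout_source,
                   src_genes, "S")
  tm <- sim_matrix(mu, tgt_types, markers, config$marker_effect,
                   config$noise_log_sd, config$depth_factor_target,
                   config$dropout_target, tgt_genes, "T")
  list(source = gene_expression_dataset(sm, labels = src_types),
       target = gene_expression_dataset(tm, labels = tgt_types),
       truth = list(markers = markers, config = config))
}
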