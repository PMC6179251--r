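# Independent brute-force oracles, deliberately written as naive double
# loops so they share no code path with the package implementation.

# Mutual information (bits) of a contingency table, by direct double-loop
# summation over all cells.
oracle_mi_from_table <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        pi_ <- sum(tab[i, ]) / n
        p_j <- sum(tab[, j]) / n
        out <- out + pij * log2(pij / (pi_ * p_j))
      }
    }
  }
  out
}

# Expand a contingency table of counts into paired (x, y) observation
# vectors.
table_to_pairs <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      k <- tab[i, j]
      x <- c(x, rep.int(i, k))
      y <- c(y, rep.int(j, k))
    }
  }
  list(x = x, y = y)
}

# AUC by exhaustive pair counting over all positive x negative pairs, ties
# counted one half.
oracle_auc_pct <- function(indicator, scores) {
  pos <- which(indicator == 1)
  neg <- which(indicator == 0)
  wins <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) wins <- wins + 1
      else if (scores[i] == scores[j]) wins <- wins + 0.5
    }
  }
  100 * wins / (length(pos) * length(neg))
}

# Top-k gene ids by pooled mean, recomputed by sorting an exhaustive
# per-gene loop; ties broken by gene id.
oracle_top_mean <- function(src_mat, tgt_mat, k) {
  means <- vapply(colnames(src_mat), function(g) {
    (sum(src_mat[, g]) + sum(tgt_mat[, g])) /
      (nrow(src_mat) + nrow(tgt_mat))
  }, numeric(1))
  df <- data.frame(g = names(means), m = means, stringsAsFactors = FALSE)
  df <- df[order(-df$m, df$g), ]
  df$g[seq_len(min(k, nrow(df)))]
}
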