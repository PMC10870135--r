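# Per-cluster expression features: mean, variance, fraction expressing and
# log2 fold change of each gene in each cluster of cells.

cluster_stats <- function(norm, counts, idx) {
  n <- length(idx)
  sub <- norm[idx, , drop = FALSE]
  mu <- Matrix::colSums(sub) / n
  if (n > 1) {
    v <- (Matrix::colSums(sub^2) - n * mu^2) / (n - 1)
    v <- pmax(v, 0) # guard tiny negative round-off
  } else {
    v <- rep(0, ncol(sub))
  }
  frac <- Matrix::colSums(counts[idx, , drop = FALSE] > 0) / n
  list(mean = mu, variance = v, frac = frac)
}

#' Per-cluster gene expression features
#'
#' For every gene and cluster computes, over log-normalized expression: the
#' arithmetic mean, the unbiased sample variance (0 for singleton clusters),
#' the fraction of cells with a nonzero raw count, and the fold change
#' `log2((mean_in + 1) / (mean_out + 1))` against all cells outside the
#' cluster.
#'
#' @param am A normalized [ann_matrix()] with at least two clusters.
#' @return A tibble with columns `gene`, `cluster`, `mean`, `variance`,
#'   `frac_expressing`, `log_fc` (one row per gene-cluster pair).
#' @export
per_cluster_features <- function(am) {
  assert_annmat(am)
  if (is.null(am$norm)) abort("run normalize_counts() before computing features")
  cl <- as.character(am$cell_meta$cluster)
  clusters <- unique(cl)
  if (length(clusters) < 2) {
    abort("fold change needs at least two clusters", class = "scprio_config_error")
  }
  total <- Matrix::colSums(am$norm)
  n_all <- nrow(am$norm)
  purrr::map_dfr(clusters, function(cc) {
    idx <- which(cl == cc)
    st <- cluster_stats(am$norm, am$counts, idx)
    mean_out <- (total - st$mean * length(idx)) / (n_all - length(idx))
    tibble(gene = am$gene_ids, cluster = cc,
           mean = unname(st$mean), variance = unname(st$variance),
           frac_expressing = unname(st$frac),
           log_fc = unname(log2((st$mean + 1) / (mean_out + 1))))
  })
}

#' Drop genes with no expression in any cluster
#'
#' Keeps genes whose mean expression is greater than 0 in at least one
#' cluster; all feature columns are subset consistently.
#'
#' @param cft A cluster feature tibble from [per_cluster_features()].
#' @return The filtered tibble.
#' @export
retain_expressed_genes <- function(cft) {
  kept <- cft |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(keep = max(.data$mean) > 0, .groups = "drop") |>
    dplyr::filter(.data$keep)
  if (nrow(kept) == 0) abort("no gene is expressed in any cluster", class = "scprio_empty_error")
  dplyr::semi_join(cft, kept, by = "gene")
}

#' Pseudo-bulk expression features
#'
#' Collapses all clusters into a single pseudo-cluster: mean, variance and
#' fraction expressing over all cells, with `log_fc` fixed at 0 (there is no
#' complement). Used by the ablation mode that mimics training on bulk-style
#' data.
#'
#' @param am A normalized [ann_matrix()].
#' @return A tibble shaped like [per_cluster_features()] with a single
#'   `"pseudobulk"` cluster.
#' @export
pseudobulk_features <- function(am) {
  assert_annmat(am)
  if (is.null(am$norm)) abort("run normalize_counts() before computing features")
  st <- cluster_stats(am$norm, am$counts, seq_len(nrow(am$norm)))
  tibble(gene = am$gene_ids, cluster = "pseudobulk",
         mean = unname(st$mean), variance = unname(st$variance),
         frac_expressing = unname(st$frac), log_fc = 0)
}
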