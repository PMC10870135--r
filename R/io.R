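#' Annotated expression matrix
#'
#' Container for a cells-by-genes expression matrix with per-cell metadata.
#' `counts` holds raw UMI counts (sparse `dgCMatrix`); `norm` holds
#' log-normalized expression once [normalize_counts()] has been called.
#' `cell_meta` is a tibble with one row per cell carrying at least `cell_id`,
#' `cluster` and `stage`, plus optional `pseudotime`, `doublet_score`,
#' `pct_mito` and `pct_ribo` columns.
#'
#' @param counts Non-negative numeric matrix, cells in rows, genes in columns.
#'   Coerced to a sparse `dgCMatrix`.
#' @param cell_meta Data frame of per-cell metadata; must have as many rows as
#'   `counts` and contain `cell_id`, `cluster` and `stage` columns.
#' @return An object of class `ann_matrix`.
#' @export
ann_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  cell_meta <- as_tibble(cell_meta)
  required <- c("cell_id", "cluster", "stage")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("cell metadata lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "scprio_schema_error")
  }
  if (nrow(cell_meta) != nrow(counts)) {
    abort(sprintf("metadata has %d rows but the matrix has %d cells",
                  nrow(cell_meta), nrow(counts)),
          class = "scprio_dim_error")
  }
  if (any(counts@x < 0)) abort("counts must be non-negative")
  gene_ids <- colnames(counts)
  if (is.null(gene_ids) || anyDuplicated(gene_ids) || any(!nzchar(gene_ids))) {
    abort("gene identifiers must be present, unique and non-empty")
  }
  rownames(counts) <- cell_meta$cell_id
  structure(
    list(counts = counts, norm = NULL, cell_meta = cell_meta, gene_ids = gene_ids),
    class = "ann_matrix"
  )
}

#' @export
print.ann_matrix <- function(x, ...) {
  cat(sprintf("<ann_matrix> %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm)) "raw counts" else "normalized"))
  cat(sprintf("  clusters: %s\n", paste(unique(x$cell_meta$cluster), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ann_matrix <- function(x) dim(x$counts)

subset_cells <- function(am, keep) {
  am$counts <- am$counts[keep, , drop = FALSE]
  if (!is.null(am$norm)) am$norm <- am$norm[keep, , drop = FALSE]
  am$cell_meta <- am$cell_meta[keep, , drop = FALSE]
  am
}

#' Read an expression matrix with cell metadata
#'
#' Reads a cells-by-genes expression matrix and its per-cell metadata into an
#' [ann_matrix()]. The Matrix Market layout follows the CellRanger convention
#' (genes as rows) and is transposed on load; a dense TSV is read with cells
#' as rows and genes as columns (gene names in the header).
#'
#' @param matrix_path Path to the matrix: a `.mtx` file (with sibling
#'   `genes.tsv` and `barcodes.tsv` in the same directory, or paths given via
#'   `genes_path`/`barcodes_path`) or a dense TSV.
#' @param cell_meta_path Path to a tab-separated cell metadata table with a
#'   header; must contain `cell_id`, `cluster` and `stage`.
#' @param format One of `"mtx"` or `"dense_tsv"`. (`"h5"` is recognized but
#'   not supported by this build and raises an error.)
#' @param genes_path,barcodes_path Optional explicit label-file paths for the
#'   MTX layout.
#' @return An [ann_matrix()] with raw counts; call [normalize_counts()] next.
#' @export
read_expression <- function(matrix_path, cell_meta_path,
                            format = c("mtx", "dense_tsv", "h5"),
                            genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (format == "h5") {
    abort("HDF5 containers are not supported by this build; use 'mtx' or 'dense_tsv'")
  }
  if (!file.exists(matrix_path)) abort(sprintf("matrix file not found: %s", matrix_path))
  if (!file.exists(cell_meta_path)) abort(sprintf("metadata file not found: %s", cell_meta_path))
  meta <- readr::read_tsv(cell_meta_path, show_col_types = FALSE, progress = FALSE)
  if (format == "mtx") {
    dir <- dirname(matrix_path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    m <- Matrix::t(readMM(matrix_path)) # CellRanger stores genes x cells
    genes <- readr::read_tsv(genes_path, col_names = FALSE, show_col_types = FALSE,
                             progress = FALSE)[[1]]
    barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE, show_col_types = FALSE,
                                progress = FALSE)[[1]]
    colnames(m) <- genes
    rownames(m) <- barcodes
  } else {
    tab <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab[[1]]
  }
  if (nrow(meta) != nrow(m)) {
    abort(sprintf("metadata has %d rows but the matrix has %d cells",
                  nrow(meta), nrow(m)),
          class = "scprio_dim_error")
  }
  ann_matrix(m, meta)
}

#' Quality-control configuration
#'
#' Cell-level QC thresholds. All comparisons are strict: a cell is retained
#' when its UMI count and detected-gene count exceed the minima and its
#' mitochondrial/ribosomal percentages and doublet score fall below the
#' maxima. Criteria whose metadata column is absent are skipped with a
#' warning.
#'
#' @param min_umi Minimum total UMI per cell (exclusive). Default 1000.
#' @param min_genes Minimum detected genes per cell (exclusive). Default 500.
#' @param max_pct_mito Maximum mitochondrial percentage (exclusive). Default 10.
#' @param max_pct_ribo Maximum ribosomal percentage (exclusive). Default 50.
#' @param max_doublet_score Maximum doublet score (exclusive). Default 0.2.
#' @param min_cluster_fraction Minimum fraction of post-QC cells a cluster
#'   must hold to be retained. Default 0.04.
#' @param excluded_clusters Character vector of cluster labels to drop.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_umi = 1000, min_genes = 500, max_pct_mito = 10,
                      max_pct_ribo = 50, max_doublet_score = 0.2,
                      min_cluster_fraction = 0.04, excluded_clusters = character()) {
  stopifnot(min_umi >= 0, min_genes >= 0, max_pct_mito >= 0, max_pct_ribo >= 0,
            max_doublet_score >= 0,
            min_cluster_fraction >= 0, min_cluster_fraction < 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_pct_mito = max_pct_mito, max_pct_ribo = max_pct_ribo,
                 max_doublet_score = max_doublet_score,
                 min_cluster_fraction = min_cluster_fraction,
                 excluded_clusters = as.character(excluded_clusters)),
            class = "qc_config")
}

#' Read a QC configuration from a YAML file
#'
#' Fields mirror the arguments of [qc_config()]; absent fields keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `qc_config` object.
#' @export
read_qc_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) abort("the 'yaml' package is required")
  vals <- yaml::read_yaml(path)
  do.call(qc_config, vals[intersect(names(vals), names(formals(qc_config)))])
}

#' Filter cells on quality-control thresholds
#'
#' Retains cells with more than `min_umi` UMIs and `min_genes` detected genes
#' and, when the columns exist, mitochondrial / ribosomal percentages and
#' doublet scores strictly below their maxima. Boundary values are removed.
#'
#' @param am An [ann_matrix()].
#' @param cfg A [qc_config()].
#' @return A filtered `ann_matrix`; cluster order is preserved.
#' @export
qc_filter <- function(am, cfg = qc_config()) {
  assert_annmat(am)
  umi <- Matrix::rowSums(am$counts)
  ngene <- Matrix::rowSums(am$counts > 0)
  keep <- umi > cfg$min_umi & ngene > cfg$min_genes
  meta <- am$cell_meta
  optional <- list(pct_mito = function(x) x < cfg$max_pct_mito,
                   pct_ribo = function(x) x < cfg$max_pct_ribo,
                   doublet_score = function(x) x < cfg$max_doublet_score)
  for (col in names(optional)) {
    if (col %in% names(meta)) {
      keep <- keep & optional[[col]](meta[[col]])
    } else {
      log_warn("column '%s' absent; skipping that QC criterion", col)
    }
  }
  if (!any(keep)) abort("QC removed every cell", class = "scprio_empty_error")
  subset_cells(am, which(keep))
}

#' Remove rare and excluded clusters
#'
#' Drops cells whose cluster holds less than `min_cluster_fraction` of the
#' (post-QC) cells, or whose cluster is listed in `excluded_clusters`.
#' Fractions are computed once on the input, not iteratively.
#'
#' @inheritParams qc_filter
#' @return A filtered `ann_matrix`.
#' @export
cluster_fraction_filter <- function(am, cfg = qc_config()) {
  assert_annmat(am)
  cl <- as.character(am$cell_meta$cluster)
  frac <- table(cl) / length(cl)
  bad <- names(frac)[frac < cfg$min_cluster_fraction]
  bad <- union(bad, cfg$excluded_clusters)
  keep <- !(cl %in% bad)
  if (!any(keep)) abort("cluster filtering removed every cell", class = "scprio_empty_error")
  subset_cells(am, which(keep))
}

#' Library-size normalize and log-transform counts
#'
#' Sets `norm[i, j] = log(1 + counts[i, j] * scale_target / library_size_i)`
#' (natural log). Stands in for variance-stabilizing transforms fitted on real
#' data; the zero pattern of the counts is preserved exactly.
#'
#' @param am An [ann_matrix()] with raw counts.
#' @param scale_target Target library size. Default `1e4`.
#' @return The `ann_matrix` with its `norm` slot populated.
#' @export
normalize_counts <- function(am, scale_target = 1e4) {
  assert_annmat(am)
  libsize <- Matrix::rowSums(am$counts)
  if (any(libsize == 0)) {
    abort("cells with zero library size present; run qc_filter() first")
  }
  norm <- am$counts
  norm@x <- log1p(norm@x * (scale_target / libsize[norm@i + 1L]))
  am$norm <- norm
  am
}

#' Write a ranked gene table
#'
#' Writes the per-gene scores of a fitted prioritization model as a TSV with
#' columns `gene_id`, `score`, `rank`, `above_threshold`, `in_training_class`,
#' sorted by descending score with ties broken lexicographically by gene id.
#'
#' @param result A `prio_fit` object (see [run_pipeline()]) or a data frame
#'   with columns `gene`, `score` and `in_training`.
#' @param path Output file path.
#' @return Invisibly, the written tibble.
#' @export
write_ranked_genes <- function(result, path) {
  if (inherits(result, "prio_fit")) {
    scores <- result$scores
    threshold <- result$threshold
  } else {
    scores <- as_tibble(result)
    threshold <- attr(result, "threshold") %||% 0.5
  }
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::transmute(
      gene_id = .data$gene,
      score = .data$score,
      rank = dplyr::row_number(),
      above_threshold = .data$score > threshold,
      in_training_class = .data$in_training
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
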