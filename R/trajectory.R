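# Pseudotime trajectory features: per-cluster pseudotime ordering, binned
# expression profiles, and clamped cubic B-spline coefficients fitted by
# ridge-stabilized least squares.

#' Assign per-cell pseudotime within each cluster
#'
#' In `"precomputed"` mode the `pseudotime` metadata column is min-max
#' rescaled to \[0, 1\] within each cluster. In `"stage_rank"` mode each cell
#' receives `(stage_index + u) / n_stages`, where stages are ordered by
#' [stage_levels()] and `u` is a within-stage offset from a seeded permutation
#' of the stage's cells, so the earliest stage occupies the lowest pseudotime
#' (the trajectory root) and values are unique.
#'
#' @param am An [ann_matrix()].
#' @param mode `"precomputed"` or `"stage_rank"`.
#' @param seed Integer seed for the stage-rank permutation.
#' @return A tibble with columns `cell_id`, `cluster`, `pseudotime`.
#' @export
assign_pseudotime <- function(am, mode = c("precomputed", "stage_rank"), seed = 1L) {
  assert_annmat(am)
  mode <- match.arg(mode)
  meta <- am$cell_meta
  if (mode == "precomputed") {
    if (!"pseudotime" %in% names(meta) || all(is.na(meta$pseudotime))) {
      abort("mode 'precomputed' requires a pseudotime metadata column",
            class = "scprio_schema_error")
    }
    out <- meta |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(pt = rescale01(.data$pseudotime)) |>
      dplyr::ungroup()
    return(tibble(cell_id = out$cell_id, cluster = as.character(out$cluster),
                  pseudotime = out$pt))
  }
  if (!"stage" %in% names(meta)) {
    abort("mode 'stage_rank' requires a stage metadata column",
          class = "scprio_schema_error")
  }
  levels_all <- stage_levels(meta$stage)
  res <- purrr::map_dfr(unique(as.character(meta$cluster)), function(cc) {
    idx <- which(as.character(meta$cluster) == cc)
    stg <- as.character(meta$stage[idx])
    lev <- levels_all[levels_all %in% stg]
    if (length(lev) == 1) {
      log_warn("cluster '%s' has a single stage; spreading cells uniformly", cc)
    }
    pt <- numeric(length(idx))
    for (si in seq_along(lev)) {
      sidx <- which(stg == lev[si])
      perm <- withr::with_seed(seed + si, sample(length(sidx)))
      u <- (perm - 0.5) / length(sidx)
      if (length(lev) == 1) {
        pt[sidx] <- u
      } else {
        pt[sidx] <- (si - 1 + u) / length(lev)
      }
    }
    tibble(cell_id = meta$cell_id[idx], cluster = cc, pseudotime = pt)
  })
  res
}

rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Bin expression along pseudotime
#'
#' Pools cells into `n_bins` equal-width half-open intervals
#' `[k/n, (k+1)/n)` on pseudotime (the last bin is closed at 1) and averages
#' each gene's normalized expression per bin. Empty bins are omitted.
#'
#' @param expr Numeric matrix of normalized expression, cells in rows and
#'   genes in columns (a single gene may be passed as a one-column matrix).
#' @param pseudotime Numeric vector in \[0, 1\], one value per row of `expr`.
#' @param n_bins Number of bins (default 20).
#' @return A tibble with columns `gene`, `bin`, `bin_center`, `bin_mean`,
#'   `n_cells`.
#' @export
bin_expression <- function(expr, pseudotime, n_bins = 20L) {
  stopifnot(n_bins >= 2, length(pseudotime) == nrow(expr))
  if (any(pseudotime < 0 | pseudotime > 1, na.rm = TRUE)) {
    abort("pseudotime must lie in [0, 1]")
  }
  bin <- pmin(floor(pseudotime * n_bins), n_bins - 1L) + 1L
  sums <- rowsum(as.matrix(expr), group = bin)
  counts <- as.vector(table(factor(bin, levels = sort(unique(bin)))))
  means <- sums / counts
  bins_present <- as.integer(rownames(sums))
  genes <- colnames(expr) %||% paste0("g", seq_len(ncol(expr)))
  tidyr::expand_grid(gene = genes, row = seq_along(bins_present)) |>
    dplyr::mutate(
      bin = bins_present[.data$row],
      bin_center = (bins_present[.data$row] - 0.5) / n_bins,
      bin_mean = purrr::map2_dbl(.data$gene, .data$row, function(g, r) means[r, g]),
      n_cells = counts[.data$row]
    ) |>
    dplyr::select(-"row") |>
    dplyr::arrange(.data$gene, .data$bin)
}

#' Clamped cubic B-spline basis
#'
#' Builds an open-uniform (clamped) B-spline basis on \[0, 1\]:
#' `degree + 1` repeated boundary knots at 0 and 1 and
#' `n_basis - degree - 1` equally spaced interior knots. The basis functions
#' form a partition of unity.
#'
#' @param degree Spline degree (default 3, cubic).
#' @param n_basis Number of basis functions / coefficients (default 10, the
#'   number of control points describing each temporal profile).
#' @return A list of class `spline_basis` with `degree`, `n_basis`, `knots`.
#' @export
build_basis <- function(degree = 3L, n_basis = 10L) {
  if (n_basis < degree + 1) {
    abort("n_basis must be at least degree + 1", class = "scprio_param_error")
  }
  n_interior <- n_basis - degree - 1L
  interior <- if (n_interior > 0) seq_len(n_interior) / (n_interior + 1) else numeric()
  knots <- c(rep(0, degree + 1), interior, rep(1, degree + 1))
  structure(list(degree = as.integer(degree), n_basis = as.integer(n_basis),
                 knots = knots),
            class = "spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis A [build_basis()] object.
#' @param t Evaluation points in \[0, 1\].
#' @return Matrix `length(t)` x `n_basis` of basis values.
#' @export
basis_matrix <- function(basis, t) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(t < 0 | t > 1)) abort("evaluation points must lie in [0, 1]")
  splines::splineDesign(basis$knots, x = t, ord = basis$degree + 1L)
}

#' Fit spline coefficients to a binned profile
#'
#' Minimizes `||B beta - y||^2 + ridge * ||beta||^2`, where `B` is the basis
#' evaluated at the bin centers and `y` the bin means. Bins are weighted
#' equally regardless of cell count. The tiny default ridge keeps the system
#' solvable when fewer bins than basis functions are available while
#' recovering the ordinary least-squares solution in the well-posed case.
#'
#' @param profile Data frame with columns `bin_center` and `bin_mean`
#'   (a single gene's profile).
#' @param basis A [build_basis()] object.
#' @param ridge Ridge penalty (default `1e-8`).
#' @return Numeric vector of length `n_basis`.
#' @export
fit_spline_coefficients <- function(profile, basis = build_basis(), ridge = 1e-8) {
  stopifnot(nrow(profile) >= 1)
  B <- basis_matrix(basis, profile$bin_center)
  solve_ridge_ls(B, matrix(profile$bin_mean, ncol = 1), ridge)[, 1]
}

# Ridge least squares via the augmented QR system; Y may hold many genes.
solve_ridge_ls <- function(B, Y, ridge) {
  p <- ncol(B)
  Baug <- rbind(B, sqrt(ridge) * diag(p))
  Yaug <- rbind(as.matrix(Y), matrix(0, p, ncol(Y)))
  qr.coef(qr(Baug), Yaug)
}

#' Trajectory spline features for every gene and cluster
#'
#' Runs, independently per cluster: pseudotime assignment, binning into
#' `n_bins` pseudotime bins, and spline-coefficient extraction for every
#' gene. Genes with no expression in a cluster receive an all-zero
#' coefficient vector (the exact fit of a zero profile).
#'
#' @inheritParams assign_pseudotime
#' @param n_bins Number of pseudotime bins (default 20).
#' @param basis A [build_basis()] object (default cubic with 10 coefficients).
#' @param ridge Ridge penalty passed to the fit.
#' @return A tibble with columns `gene`, `cluster`, `coef_0` ... `coef_<n-1>`.
#' @export
trajectory_features <- function(am, mode = c("precomputed", "stage_rank"),
                                n_bins = 20L, basis = build_basis(),
                                seed = 1L, ridge = 1e-8) {
  assert_annmat(am)
  if (is.null(am$norm)) abort("run normalize_counts() before computing features")
  mode <- match.arg(mode)
  pt <- assign_pseudotime(am, mode, seed)
  cl <- as.character(am$cell_meta$cluster)
  coef_names <- paste0("coef_", seq_len(basis$n_basis) - 1L)
  purrr::map_dfr(unique(cl), function(cc) {
    idx <- which(cl == cc)
    ptc <- pt$pseudotime[match(am$cell_meta$cell_id[idx], pt$cell_id)]
    expr <- as.matrix(am$norm[idx, , drop = FALSE])
    bin <- pmin(floor(ptc * n_bins), n_bins - 1L) + 1L
    sums <- rowsum(expr, group = bin)
    counts <- as.vector(table(factor(bin, levels = sort(unique(bin)))))
    means <- sums / counts
    centers <- (as.integer(rownames(sums)) - 0.5) / n_bins
    B <- basis_matrix(basis, centers)
    beta <- t(solve_ridge_ls(B, means, ridge)) # genes x n_basis
    colnames(beta) <- coef_names
    dplyr::bind_cols(tibble(gene = am$gene_ids, cluster = cc), as_tibble(beta))
  })
}
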