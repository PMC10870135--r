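# End-to-end prioritization: QC -> features -> classes -> classifier ->
# threshold -> genome-wide ranking, with feature-block ablations.

#' Run the full gene-prioritization pipeline
#'
#' Conditions the expression data (QC, rare-cluster removal, log
#' normalization), computes the per-cluster and trajectory feature blocks,
#' builds the training classes, and runs the classification pipeline:
#' chained-equations imputation, min-max scaling, recall-optimized grid
#' search with ADASYN class balancing inside training folds, out-of-fold
#' validation, density-zero thresholding, and scoring of every gene.
#'
#' @param am An [ann_matrix()] (raw counts; QC and normalization are applied
#'   here unless `qc` is `NULL` and the matrix is already normalized).
#' @param props Gene-property tibble ([merge_properties()]).
#' @param disease_genes Character vector: known disease-associated genes.
#' @param housekeeping Character vector: housekeeping genes.
#' @param ref Reference pseudobulk for the ubiquity filter.
#' @param qc A [qc_config()], or `NULL` to skip cell filtering.
#' @param mode Feature ablation mode: `"full"` (cluster + trajectory +
#'   gene-intrinsic blocks), `"no_trajectory"` (cluster + gene-intrinsic),
#'   `"cluster_only"` (cluster block alone) or `"pseudobulk_only"`
#'   (all-cells pseudo-bulk block alone).
#' @param pseudotime_mode Passed to [assign_pseudotime()].
#' @param n_bins,basis Trajectory binning and spline basis settings.
#' @param grid A [hyperparameter_grid()].
#' @param folds CV folds (default 5).
#' @param seed Integer seed governing every random step.
#' @param grid_step,eps_frac Threshold-selection settings
#'   ([density_zero_threshold()]).
#' @return An object of class `prio_fit`; see [tidy.prio_fit()],
#'   [glance.prio_fit()], [autoplot.prio_fit()].
#' @export
run_pipeline <- function(am, props, disease_genes, housekeeping, ref,
                         qc = qc_config(),
                         mode = c("full", "no_trajectory", "cluster_only", "pseudobulk_only"),
                         pseudotime_mode = c("precomputed", "stage_rank"),
                         n_bins = 20L, basis = build_basis(),
                         grid = hyperparameter_grid(), folds = 5L, seed = 1L,
                         grid_step = 0.001, eps_frac = 1e-3) {
  mode <- match.arg(mode)
  pseudotime_mode <- match.arg(pseudotime_mode)
  if (!is.null(qc)) {
    am <- qc_filter(am, qc)
    am <- cluster_fraction_filter(am, qc)
  }
  if (is.null(am$norm)) am <- normalize_counts(am)

  if (mode == "pseudobulk_only") {
    cft <- retain_expressed_genes(pseudobulk_features(am))
  } else {
    cft <- retain_expressed_genes(per_cluster_features(am))
  }
  tft <- if (mode == "full") {
    trajectory_features(am, mode = pseudotime_mode, n_bins = n_bins,
                        basis = basis, seed = seed)
  } else NULL
  use_props <- if (mode %in% c("full", "no_trajectory")) props else NULL

  classes <- build_training_classes(disease_genes, housekeeping, ref, props)
  fm <- assemble_features(cft, tft, use_props, classes)
  fm <- iterative_impute(fm)
  labeled <- fm$label != "unlabeled"
  if (sum(labeled) == 0) abort("no labeled gene retained", class = "scprio_config_error")
  fm_lab <- fm[labeled, ]
  attr(fm_lab, "groups") <- attr(fm, "groups")
  fm_lab_scaled <- minmax_scale(fm_lab)
  scaling <- attr(fm_lab_scaled, "scaling")
  fm_all_scaled <- minmax_scale(fm, params = scaling)

  X <- fm_matrix(fm_lab_scaled)
  y <- fm_lab_scaled$label
  best <- grid_search(X, y, grid, folds = folds, seed = seed + 1L)
  cv <- cross_validated_metrics(X, y, best, folds = folds, seed = seed + 2L)
  model <- train_final_model(X, y, best, seed = seed + 3L)
  threshold <- density_zero_threshold(cv$oof$score[cv$oof$label == "negative"],
                                      grid_step = grid_step, eps_frac = eps_frac)
  pred <- predict_all(model, fm_all_scaled, classes, threshold)
  groups <- attr(fm, "groups")
  importances <- model$importances |>
    dplyr::mutate(group = unname(groups[.data$feature]))
  oof <- dplyr::bind_cols(tibble(gene = fm_lab$gene), cv$oof)

  structure(list(
    mode = mode,
    best_params = best,
    cv_metrics = cv$metrics,
    roc_points = cv$roc_points,
    auc = cv$auc,
    oof = oof,
    feature_importances = importances,
    group_importances = group_importances(model$importances, groups),
    model = model,
    scaling = scaling,
    threshold = threshold,
    scores = pred$scores,
    candidates = pred$candidates,
    classes = classes,
    seed = seed
  ), class = "prio_fit")
}

#' Re-run the pipeline restricted to a feature block
#'
#' Convenience wrapper over [run_pipeline()] for side-by-side ablation
#' comparisons (`"pseudobulk_only"` mimics training on bulk-style data;
#' `"cluster_only"` drops the temporal block; `"no_trajectory"` keeps
#' cluster and gene-intrinsic blocks).
#'
#' @inheritParams run_pipeline
#' @param ... Passed on to [run_pipeline()].
#' @return A `prio_fit`.
#' @export
ablation_run <- function(am, props, disease_genes, housekeeping, ref,
                         mode, ...) {
  run_pipeline(am, props, disease_genes, housekeeping, ref, mode = mode, ...)
}

#' @export
print.prio_fit <- function(x, ...) {
  cat(sprintf("<prio_fit> mode = %s\n", x$mode))
  cat(sprintf("  CV: AUC %.4f | sensitivity %.4f | precision %.4f | accuracy %.4f\n",
              x$auc, x$cv_metrics$sensitivity, x$cv_metrics$precision,
              x$cv_metrics$accuracy))
  cat(sprintf("  threshold %.3f -> %d candidate genes (of %d scored)\n",
              x$threshold, nrow(x$candidates), nrow(x$scores)))
  invisible(x)
}

#' Tidy per-gene scores of a fitted prioritization model
#'
#' @param x A `prio_fit`.
#' @param ... Unused.
#' @return A tibble with one row per scored gene: `gene`, `score`, `label`,
#'   `in_training`, `candidate`, `rank` (descending score, ties by gene id).
#' @exportS3Method generics::tidy
tidy.prio_fit <- function(x, ...) {
  x$scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' One-row model summary
#'
#' @param x A `prio_fit`.
#' @param ... Unused.
#' @return A one-row tibble: CV metrics, threshold, class and candidate
#'   counts, and the selected hyperparameters.
#' @exportS3Method generics::glance
glance.prio_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$cv_metrics,
    tibble(threshold = x$threshold,
           n_positive = length(x$classes$positive),
           n_negative = length(x$classes$negative),
           n_candidates = nrow(x$candidates)),
    as_tibble(x$best_params[c("adasyn_n_neighbors", "n_estimators", "max_depth",
                              "min_samples_split", "min_samples_leaf")])
  )
}

#' Score-density plot of a fitted model
#'
#' Densities of out-of-fold scores for the two training classes and of final
#' scores for unlabeled genes, with the decision threshold marked.
#'
#' @param object A `prio_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prio_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$oof |> dplyr::transmute(.data$score, group = .data$label),
    object$scores |> dplyr::filter(.data$label == "unlabeled") |>
      dplyr::transmute(.data$score, group = "unlabeled")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, bw = "nrd0") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "disease-association score", y = "density",
                  fill = NULL,
                  title = sprintf("Score distributions (threshold %.3f)", object$threshold)) +
    ggplot2::theme_minimal()
}

#' ROC curve of the cross-validated classifier
#'
#' @param fit A `prio_fit`.
#' @return A ggplot object.
#' @export
plot_roc <- function(fit) {
  ggplot2::ggplot(fit$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Out-of-fold ROC (AUC %.3f)", fit$auc)) +
    ggplot2::theme_minimal()
}

#' Feature-importance plot
#'
#' @param fit A `prio_fit`.
#' @param top_n Number of top features to show (default 20).
#' @return A ggplot object.
#' @export
plot_importance <- function(fit, top_n = 20L) {
  df <- fit$feature_importances |>
    dplyr::slice_max(.data$importance, n = top_n) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized importance", y = NULL, fill = "block") +
    ggplot2::theme_minimal()
}

#' Persist / restore a trained model
#'
#' The model is stored with a format version and its feature schema;
#' [predict_all()] (and [load_model()]) refuse schema mismatches.
#'
#' @param model A `prio_model` from [train_final_model()].
#' @param path File path.
#' @return `save_model()`: the path, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "prio_model"))
  saveRDS(list(format = "scprio_model", version = 1L,
               schema_hash = rlang::hash(model$features), model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "scprio_model")) abort("not a scprio model file")
  if (!identical(obj$schema_hash, rlang::hash(obj$model$features))) {
    abort("model schema hash mismatch; file corrupted or edited",
          class = "scprio_schema_error")
  }
  obj$model
}
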