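# Classification pipeline: feature assembly, chained-equations imputation,
# min-max scaling, adaptive synthetic oversampling, recall-optimized grid
# search over a balanced random forest, out-of-fold validation metrics, the
# density-zero decision threshold, and genome-wide scoring.

#' Assemble the per-gene feature matrix
#'
#' Joins the cluster-level expression block (`sc.mean.<cluster>`,
#' `sc.var.<cluster>`, `sc.frac.<cluster>`, `sc.fc.<cluster>`), the trajectory
#' spline block (`traj.<cluster>.coef_<k>`) and the gene-intrinsic block
#' (`prop.*`) into one row per gene, attaching training labels. Column order
#' is deterministic; missing property or trajectory cells stay `NA` for
#' imputation. The feature-to-group mapping is stored in the `"groups"`
#' attribute.
#'
#' @param cft Cluster feature tibble ([per_cluster_features()]), already
#'   passed through [retain_expressed_genes()].
#' @param tft Trajectory feature tibble ([trajectory_features()]) or `NULL`.
#' @param props Gene-property tibble ([merge_properties()]) or `NULL`.
#' @param classes A [build_training_classes()] object, or `NULL` for
#'   unlabeled assembly.
#' @return A tibble with columns `gene`, `label`
#'   (`"positive"`/`"negative"`/`"unlabeled"`) and one column per feature.
#' @export
assemble_features <- function(cft, tft = NULL, props = NULL, classes = NULL) {
  genes <- sort(unique(cft$gene))
  clusters <- unique(cft$cluster)
  sc_wide <- cft |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "cluster",
                       values_from = c("mean", "variance", "frac_expressing", "log_fc"),
                       names_glue = "{.value}.{cluster}") |>
    dplyr::rename_with(~ paste0("sc.", sub("^mean\\.", "mean.",
                         sub("^variance\\.", "var.",
                         sub("^frac_expressing\\.", "frac.",
                         sub("^log_fc\\.", "fc.", .x))))), -"gene")
  sc_cols <- unlist(lapply(clusters, function(cc)
    paste0("sc.", c("mean", "var", "frac", "fc"), ".", cc)))
  fm <- tibble(gene = genes) |> dplyr::left_join(sc_wide, by = "gene")
  fm <- fm[c("gene", sc_cols)]
  groups <- setNames(rep("sc_expression", length(sc_cols)), sc_cols)
  if (!is.null(tft)) {
    coef_cols <- grep("^coef_", names(tft), value = TRUE)
    tw <- tft |>
      tidyr::pivot_wider(id_cols = "gene", names_from = "cluster",
                         values_from = dplyr::all_of(coef_cols),
                         names_glue = "traj.{cluster}.{.value}")
    traj_cols <- unlist(lapply(unique(tft$cluster), function(cc)
      paste0("traj.", cc, ".", coef_cols)))
    fm <- dplyr::left_join(fm, tw[c("gene", traj_cols)], by = "gene")
    groups <- c(groups, setNames(rep("trajectory", length(traj_cols)), traj_cols))
  }
  if (!is.null(props)) {
    prop_order <- intersect(c(CONSTRAINT_COLS, "gc_gene", "gc_promoter",
                              "ortholog_confidence"), names(props))
    pw <- as_tibble(props)[c("gene", prop_order)]
    names(pw)[-1] <- paste0("prop.", prop_order)
    fm <- dplyr::left_join(fm, pw, by = "gene")
    groups <- c(groups, setNames(rep("gene_intrinsic", length(prop_order)),
                                 paste0("prop.", prop_order)))
  }
  label <- rep("unlabeled", length(genes))
  if (!is.null(classes)) {
    label[genes %in% classes$positive] <- "positive"
    label[genes %in% classes$negative] <- "negative"
    if (!any(label != "unlabeled")) {
      abort("no labeled gene in the feature matrix", class = "scprio_config_error")
    }
  }
  fm <- dplyr::mutate(fm, label = label, .after = "gene")
  attr(fm, "groups") <- groups
  fm
}

#' Chained-equations imputation of missing feature cells
#'
#' Missing cells are initialized with column means; then, cycling over
#' columns with missingness in fixed column order, each column is regressed
#' (ordinary least squares with intercept) on all other columns using its
#' observed rows, and its missing cells are overwritten with predictions.
#' Iteration stops when the largest absolute change of any imputed cell is
#' below `tol` or after `max_iter` sweeps. Observed cells are never modified.
#' Columns that are entirely missing are dropped with a warning.
#'
#' @param fm Feature matrix tibble from [assemble_features()].
#' @param max_iter Maximum sweeps (default 10).
#' @param tol Convergence tolerance on imputed values (default 1e-3).
#' @return The imputed feature matrix (same class/attributes).
#' @export
iterative_impute <- function(fm, max_iter = 10L, tol = 1e-3) {
  groups <- attr(fm, "groups")
  X <- fm_matrix(fm)
  all_missing <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_missing) > 0) {
    log_warn("dropping entirely missing column(s): %s", paste(all_missing, collapse = ", "))
    X <- X[, setdiff(colnames(X), all_missing), drop = FALSE]
    groups <- groups[colnames(X)]
  }
  miss <- is.na(X)
  mcols <- which(colSums(miss) > 0)
  if (length(mcols) > 0) {
    for (j in mcols) X[miss[, j], j] <- mean(X[!miss[, j], j])
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in mcols) {
        obs <- !miss[, j]
        A <- cbind(1, X[, -j, drop = FALSE])
        beta <- qr.coef(qr(A[obs, , drop = FALSE]), X[obs, j])
        beta[is.na(beta)] <- 0 # rank-deficient predictors contribute nothing
        pred <- A[!obs, , drop = FALSE] %*% beta
        delta <- max(delta, max(abs(pred - X[!obs, j])))
        X[!obs, j] <- pred
      }
      if (delta < tol) break
    }
  }
  out <- dplyr::bind_cols(fm[c("gene", "label")], as_tibble(X))
  attr(out, "groups") <- groups
  out
}

#' Min-max scale features to \[0, 1\]
#'
#' Maps every column by `(x - min) / (max - min)`. Constant columns map to 0
#' with a warning. When `params` (from a previous call, stored in the
#' `"scaling"` attribute) is supplied, the stored training minima/maxima are
#' applied instead and results are clipped to \[0, 1\] — use this to
#' transform unlabeled genes with training-derived parameters.
#'
#' @param fm Imputed feature matrix tibble (no missing cells).
#' @param params Optional scaling-parameter tibble (`feature`, `min`, `max`).
#' @return Scaled feature matrix; scaling parameters in `attr(., "scaling")`.
#' @export
minmax_scale <- function(fm, params = NULL) {
  X <- fm_matrix(fm)
  if (is.null(params)) {
    mins <- apply(X, 2, min)
    maxs <- apply(X, 2, max)
    if (any(maxs == mins)) {
      log_warn("%d constant column(s) scaled to 0", sum(maxs == mins))
    }
    params <- tibble(feature = colnames(X), min = unname(mins), max = unname(maxs))
  }
  idx <- match(colnames(X), params$feature)
  if (anyNA(idx)) {
    abort(sprintf("features absent from scaling parameters: %s",
                  paste(colnames(X)[is.na(idx)], collapse = ", ")),
          class = "scprio_schema_error")
  }
  rng <- params$max[idx] - params$min[idx]
  Xs <- sweep(X, 2, params$min[idx])
  Xs <- sweep(Xs, 2, ifelse(rng == 0, 1, rng), "/")
  Xs[, rng == 0] <- 0
  Xs <- pmin(pmax(Xs, 0), 1)
  out <- dplyr::bind_cols(fm[c("gene", "label")], as_tibble(Xs))
  attr(out, "groups") <- attr(fm, "groups")
  attr(out, "scaling") <- params
  out
}

#' Adaptive synthetic minority oversampling (ADASYN)
#'
#' Balances a two-class dataset by interpolating synthetic minority samples.
#' For each minority point, the fraction of majority points among its `k`
#' nearest neighbors in the full data weights how many synthetic points it
#' spawns (harder-to-learn regions get more); each synthetic point is
#' `x_i + lambda * (x_z - x_i)` with `x_z` one of the `k` nearest minority
#' neighbors and `lambda ~ U(0, 1)`. After ratio-weighted allocation the
#' total is trimmed or topped up (seeded, uniformly) so both classes end up
#' exactly equal in size.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Factor or character vector of two class labels.
#' @param k Neighbor count (default 5); reduced with a warning when the
#'   minority class is smaller than `k + 1`.
#' @param seed Integer seed.
#' @return A list with `X` (original rows first, then synthetic), `y`, and
#'   `synthetic` (logical marker per row).
#' @export
adasyn_oversample <- function(X, y, k = 5L, seed = 1L) {
  y <- as.character(y)
  tab <- sort(table(y))
  if (length(tab) != 2) abort("ADASYN needs exactly two classes")
  minority <- names(tab)[1]
  G <- unname(tab[2] - tab[1])
  if (G == 0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  min_idx <- which(y == minority)
  if (length(min_idx) < k + 1) {
    k_new <- length(min_idx) - 1L
    log_warn("minority class of %d smaller than k + 1; reducing k to %d",
             length(min_idx), k_new)
    k <- k_new
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  # ratio of majority members among each minority point's k nearest neighbors
  r <- vapply(min_idx, function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    sum(y[nb] != minority) / k
  }, numeric(1))
  w <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  g <- round(w * G)
  synth <- withr::with_seed(seed, {
    rows <- list()
    make_point <- function(i) {
      nb_min <- min_idx[order(D[i, min_idx])[seq_len(k)]]
      xz <- X[sample(nb_min, 1), ]
      lambda <- runif(1)
      X[i, ] + lambda * (xz - X[i, ])
    }
    for (m in seq_along(min_idx)) {
      for (s in seq_len(g[m])) rows[[length(rows) + 1L]] <- make_point(min_idx[m])
    }
    n_have <- length(rows)
    if (n_have > G) {
      rows <- rows[sort(sample(n_have, G))]
    } else if (n_have < G) {
      extra <- sample(min_idx, G - n_have, replace = TRUE)
      for (i in extra) rows[[length(rows) + 1L]] <- make_point(i)
    }
    do.call(rbind, rows)
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, G)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, G)))
}

#' Hyperparameter grid for the balanced random forest
#'
#' Defaults are a small neighborhood around the settings selected for the
#' published limb and heart models (`n_estimators` 130/90, `max_depth` 15/30,
#' `min_samples_split` 2/5, `min_samples_leaf` 1, ADASYN `k` 10/5).
#'
#' @param adasyn_n_neighbors,n_estimators,max_depth,min_samples_split,min_samples_leaf
#'   Positive-integer vectors of candidate values.
#' @return A list of class `hyper_grid`.
#' @export
hyperparameter_grid <- function(adasyn_n_neighbors = c(5L, 10L),
                                n_estimators = c(90L, 130L),
                                max_depth = c(15L, 30L),
                                min_samples_split = c(2L, 5L),
                                min_samples_leaf = 1L) {
  g <- list(adasyn_n_neighbors = adasyn_n_neighbors, n_estimators = n_estimators,
            max_depth = max_depth, min_samples_split = min_samples_split,
            min_samples_leaf = min_samples_leaf)
  stopifnot(all(vapply(g, function(v) length(v) > 0 && all(v >= 1), logical(1))))
  structure(g, class = "hyper_grid")
}

rf_fit <- function(X, y, params, seed) {
  df <- as.data.frame(X)
  df$.class <- factor(y, levels = c("negative", "positive"))
  ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = params$n_estimators, max.depth = params$max_depth,
    min.node.size = params$min_samples_split, min.bucket = params$min_samples_leaf,
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
}

rf_prob <- function(model, X) {
  unname(predict(model, data = as.data.frame(X), num.threads = 1)$predictions[, "positive"])
}

#' Grid search maximizing positive-class recall
#'
#' Exhaustively evaluates the Cartesian hyperparameter grid by stratified
#' k-fold cross-validation. Oversampling is fit inside each training fold
#' only — validation folds never contain synthetic points. The score is the
#' mean recall of the positive class at the provisional 0.5 cut; ties keep
#' the earliest grid row.
#'
#' @param X Scaled feature matrix (labeled genes only).
#' @param y Class labels (`"positive"`/`"negative"`).
#' @param grid A [hyperparameter_grid()].
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed (folds, oversampling and forests all derive from
#'   it).
#' @return Named list of the selected hyperparameters, with the full search
#'   table in `attr(., "search")`.
#' @export
grid_search <- function(X, y, grid = hyperparameter_grid(), folds = 5L, seed = 1L) {
  settings <- expand.grid(unclass(grid), KEEP.OUT.ATTRS = FALSE)
  fold_id <- stratified_folds(y, folds, seed)
  recalls <- vapply(seq_len(nrow(settings)), function(si) {
    p <- as.list(settings[si, ])
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      bal <- adasyn_oversample(X[tr, , drop = FALSE], y[tr],
                               k = p$adasyn_n_neighbors, seed = seed + f)
      fit <- rf_fit(bal$X, bal$y, p, seed = seed + 100 * si + f)
      prob <- rf_prob(fit, X[!tr, , drop = FALSE])
      pos <- y[!tr] == "positive"
      sum(prob[pos] > 0.5) / sum(pos)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(recalls) # ties: first (grid iteration order)
  out <- as.list(settings[best, ])
  attr(out, "search") <- dplyr::bind_cols(as_tibble(settings), mean_recall = recalls)
  out
}

#' Train the final balanced random forest
#'
#' Balances the full labeled set with ADASYN at the selected neighbor count,
#' then grows the forest (bootstrap resampling, impurity splitting) with the
#' selected hyperparameters. Feature importances are normalized mean
#' impurity decreases summing to 1.
#'
#' @inheritParams grid_search
#' @param params Selected hyperparameters (named list, see
#'   [hyperparameter_grid()] fields).
#' @return A list of class `prio_model`: the `ranger` forest, normalized
#'   `importances` tibble, `params`, `features` (schema), and `seed`.
#' @export
train_final_model <- function(X, y, params, seed = 1L) {
  bal <- adasyn_oversample(X, y, k = params$adasyn_n_neighbors, seed = seed)
  fit <- rf_fit(bal$X, bal$y, params, seed = seed)
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  structure(list(forest = fit,
                 importances = tibble(feature = names(imp), importance = unname(imp)),
                 params = params, features = colnames(X), seed = seed),
            class = "prio_model")
}

#' Out-of-fold cross-validated metrics
#'
#' Stratified k-fold CV at fixed hyperparameters; oversampling inside
#' training folds only. Every labeled gene receives one out-of-fold
#' probability. Accuracy, sensitivity (positive recall) and precision are
#' computed at the provisional 0.5 cut; the ROC curve and AUC come from the
#' standard threshold sweep over the out-of-fold scores.
#'
#' @inheritParams train_final_model
#' @param folds Number of folds (default 5).
#' @return A list: `metrics` (one-row tibble), `oof` (tibble `gene`
#'   omitted — `label`, `score`, `fold`), `roc_points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`.
#' @export
cross_validated_metrics <- function(X, y, params, folds = 5L, seed = 1L) {
  fold_id <- stratified_folds(y, folds, seed)
  score <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    bal <- adasyn_oversample(X[tr, , drop = FALSE], y[tr],
                             k = params$adasyn_n_neighbors, seed = seed + f)
    fit <- rf_fit(bal$X, bal$y, params, seed = seed + f)
    score[!tr] <- rf_prob(fit, X[!tr, , drop = FALSE])
  }
  pred_pos <- score > 0.5
  is_pos <- y == "positive"
  metrics <- tibble(
    accuracy = mean(pred_pos == is_pos),
    sensitivity = sum(pred_pos & is_pos) / sum(is_pos),
    precision = if (sum(pred_pos) == 0) NA_real_ else sum(pred_pos & is_pos) / sum(pred_pos)
  )
  sweep <- roc_sweep(y, score)
  metrics$roc_auc <- attr(sweep, "auc")
  roc_points <- sweep
  list(metrics = metrics,
       oof = tibble(label = y, score = score, fold = fold_id),
       roc_points = roc_points, auc = metrics$roc_auc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Standard sweep over all score thresholds (positive called when
#' `score > threshold`), giving the ROC step curve and its area.
#'
#' @param y Labels (`"positive"`/`"negative"`).
#' @param score Numeric scores, higher meaning more positive.
#' @return Tibble `threshold`, `fpr`, `tpr` ordered along the curve, with the
#'   AUC in `attr(., "auc")`.
#' @export
roc_sweep <- function(y, score) {
  roc <- pROC::roc(response = y, predictor = score,
                   levels = c("negative", "positive"), direction = "<", quiet = TRUE)
  out <- tibble(threshold = roc$thresholds,
                fpr = 1 - roc$specificities, tpr = roc$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  attr(out, "auc") <- as.numeric(pROC::auc(roc))
  out
}

#' Density-zero decision threshold
#'
#' Estimates a Gaussian kernel density (Silverman's bandwidth) of the
#' negative class's out-of-fold scores on the grid \[0, 1\] and returns the
#' smallest grid point at or above the negative-score mode where the density
#' falls below `eps_frac` times its maximum — the score beyond which the
#' negative class has effectively zero density. Falls back to the 99.5th
#' percentile of the negative scores when no grid point qualifies.
#'
#' @param neg_scores Out-of-fold scores of negative-class genes (>= 10).
#' @param grid_step Evaluation grid step (default 0.001).
#' @param eps_frac Fraction of the density maximum treated as zero
#'   (default 1e-3).
#' @return Threshold in \[0, 1\].
#' @export
density_zero_threshold <- function(neg_scores, grid_step = 0.001, eps_frac = 1e-3) {
  if (length(neg_scores) < 10) abort("need at least 10 negative scores")
  if (length(unique(neg_scores)) == 1) {
    log_warn("all negative scores identical; threshold set just above them")
    return(min(1, neg_scores[1] + grid_step))
  }
  n_grid <- round(1 / grid_step) + 1
  d <- density(neg_scores, bw = bw.nrd0(neg_scores), kernel = "gaussian",
               from = 0, to = 1, n = n_grid)
  mode_i <- which.max(d$y)
  cut <- eps_frac * max(d$y)
  after <- which(d$y < cut & seq_along(d$y) >= mode_i)
  if (length(after) == 0) {
    return(unname(quantile(neg_scores, 0.995)))
  }
  min(1, max(0, d$x[min(after)]))
}

#' Score all genes and extract candidates
#'
#' Applies a trained model to the full (imputed, training-scaled) feature
#' matrix. Every gene is scored; candidates are the unlabeled genes with
#' score above the threshold, ranked by descending score (ties broken
#' lexicographically by gene id). Training-class genes are scored but flagged
#' and excluded from the candidate list.
#'
#' @param model A [train_final_model()] object.
#' @param fm_all Imputed and scaled feature matrix for all genes.
#' @param classes A [build_training_classes()] object.
#' @param threshold Decision threshold from [density_zero_threshold()].
#' @return A list: `scores` (tibble `gene`, `score`, `label`, `in_training`,
#'   `candidate`) and `candidates` (ranked tibble of candidate genes).
#' @export
predict_all <- function(model, fm_all, classes, threshold) {
  stopifnot(inherits(model, "prio_model"))
  X <- fm_matrix(fm_all)
  if (!identical(colnames(X), model$features)) {
    differing <- c(setdiff(model$features, colnames(X)), setdiff(colnames(X), model$features))
    abort(sprintf("feature schema mismatch between training and prediction: %s",
                  paste(differing, collapse = ", ")),
          class = "scprio_schema_error")
  }
  score <- rf_prob(model$forest, X)
  in_training <- fm_all$gene %in% c(classes$positive, classes$negative)
  scores <- tibble(gene = fm_all$gene, score = score, label = fm_all$label,
                   in_training = in_training,
                   candidate = !in_training & score > threshold)
  candidates <- scores |>
    dplyr::filter(.data$candidate) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(scores = scores, candidates = candidates)
}

#' Aggregate feature importances by feature group
#'
#' Reports, per feature block (`sc_expression`, `trajectory`,
#' `gene_intrinsic`), both the sum of normalized importances and the mean of
#' squared importances scaled by 1000 (two common aggregates; both are
#' labeled in the output).
#'
#' @param importances Tibble `feature`, `importance` (normalized).
#' @param groups Named character vector mapping feature name to group.
#' @return A tibble `group`, `importance_sum`, `mean_square_x1000`.
#' @export
group_importances <- function(importances, groups) {
  unknown <- setdiff(importances$feature, names(groups))
  if (length(unknown) > 0) {
    abort(sprintf("feature(s) not assignable to a group: %s",
                  paste(unknown, collapse = ", ")),
          class = "scprio_schema_error")
  }
  importances |>
    dplyr::mutate(group = unname(groups[.data$feature])) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(importance_sum = sum(.data$importance),
                     mean_square_x1000 = mean(.data$importance^2) * 1000,
                     .groups = "drop")
}
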