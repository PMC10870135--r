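make_cft <- function(genes, clusters) {
  tidyr::expand_grid(gene = genes, cluster = clusters) |>
    dplyr::mutate(mean = seq_along(gene), variance = 1, frac_expressing = 0.5,
                  log_fc = 0)
}

make_tft <- function(genes, clusters, n_basis = 10) {
  tft <- tidyr::expand_grid(gene = genes, cluster = clusters)
  for (k in seq_len(n_basis) - 1) tft[[paste0("coef_", k)]] <- k + 0.0
  tft
}

make_props <- function(genes) {
  tibble::tibble(gene = genes, pLI = 0.5, pRec = 0.25, pNull = 0.25,
                 syn_z = 0, mis_z = 0, lof_z = 0, gc_gene = 0.4, gc_promoter = 0.5,
                 ortholog_confidence = 1)
}

test_that("feature assembly produces the documented column layout deterministically", {
  genes <- paste0("g", 1:6)
  classes <- structure(list(positive = "g1", negative = c("g2", "g3"),
                            provenance = tibble::tibble()),
                       class = "training_classes")
  fm <- assemble_features(make_cft(genes, paste0("c", 1:3)),
                          make_tft(genes, paste0("c", 1:3)),
                          make_props(genes), classes)
  expect_identical(ncol(fm) - 2L, 3L * 4L + 3L * 10L + 9L) # 51 feature columns
  expect_identical(fm$label, c("positive", "negative", "negative",
                               "unlabeled", "unlabeled", "unlabeled"))
  groups <- attr(fm, "groups")
  expect_identical(as.integer(table(groups)[c("sc_expression", "trajectory", "gene_intrinsic")]),
                   c(12L, 30L, 9L))

  fm2 <- assemble_features(make_cft(genes, paste0("c", 1:3)),
                           make_tft(genes, paste0("c", 1:3)),
                           make_props(genes), classes)
  expect_identical(fm, fm2)

  # a gene absent from the property table gets a missing property block
  props5 <- make_props(genes[1:5])
  fm3 <- assemble_features(make_cft(genes, paste0("c", 1:3)),
                           make_tft(genes, paste0("c", 1:3)), props5, classes)
  expect_identical(sum(is.na(fm3[fm3$gene == "g6", grepl("^prop", names(fm3))])), 9L)
})

test_that("imputation recovers exact linear relations and never touches observed cells", {
  set.seed(2)
  n <- 40
  x1 <- rnorm(n)
  fm <- tibble::tibble(gene = paste0("g", 1:n), label = "unlabeled",
                       f1 = x1, f2 = 3 * x1 - 1, f3 = rnorm(n))
  attr(fm, "groups") <- setNames(rep("sc_expression", 3), c("f1", "f2", "f3"))
  complete <- iterative_impute(fm)
  expect_equal(as.data.frame(complete), as.data.frame(fm), ignore_attr = TRUE)

  fm_miss <- fm
  fm_miss$f2[5] <- NA
  out <- iterative_impute(fm_miss, max_iter = 25, tol = 1e-10)
  expect_equal(out$f2[5], 3 * x1[5] - 1, tolerance = 1e-6)
  expect_identical(out$f2[-5], fm$f2[-5])
  expect_identical(out$f1, fm$f1)

  fm_all_na <- fm
  fm_all_na$f3 <- NA_real_
  expect_warning(dropped <- iterative_impute(fm_all_na), regexp = "f3")
  expect_false("f3" %in% names(dropped))
})

test_that("min-max scaling maps to [0, 1], flags constants and clips new data", {
  fm <- tibble::tibble(gene = c("a", "b", "c"), label = "unlabeled",
                       u = c(2, 4, 6), k = c(5, 5, 5))
  expect_warning(sc <- minmax_scale(fm), regexp = "constant")
  expect_equal(sc$u, c(0, 0.5, 1))
  expect_equal(sc$k, c(0, 0, 0))

  new <- tibble::tibble(gene = "d", label = "unlabeled", u = 10, k = 5)
  out <- minmax_scale(new, params = attr(sc, "scaling"))
  expect_equal(out$u, 1) # clipped
  expect_true(all(out$k >= 0 & out$k <= 1))
})

test_that("ADASYN balances classes exactly with synthetic convex combinations", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20 * 2), ncol = 2),        # minority around 0
             matrix(rnorm(60 * 2, mean = 3), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- c(rep("positive", 20), rep("negative", 60))
  out <- adasyn_oversample(X, y, k = 5, seed = 9)
  expect_identical(as.integer(table(out$y)), c(60L, 60L))
  expect_identical(sum(out$synthetic), 40L)

  # every synthetic point is a convex combination of two real minority points
  minX <- X[y == "positive", , drop = FALSE]
  synth <- out$X[out$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    resid <- Inf
    for (a in seq_len(nrow(minX))) {
      for (b in seq_len(nrow(minX))) {
        d <- minX[b, ] - minX[a, ]
        lam <- if (sum(d^2) == 0) 0 else sum((s - minX[a, ]) * d) / sum(d^2)
        if (lam >= -1e-9 && lam <= 1 + 1e-9) {
          resid <- min(resid, sqrt(sum((s - (minX[a, ] + lam * d))^2)))
        }
      }
    }
    expect_lt(resid, 1e-10)
  }

  # balanced input passes through untouched
  yb <- rep(c("positive", "negative"), each = 40)
  outb <- adasyn_oversample(X, yb, k = 5, seed = 9)
  expect_identical(outb$X, X)
  # determinism
  out2 <- adasyn_oversample(X, y, k = 5, seed = 9)
  expect_identical(out$X, out2$X)
})

test_that("grid search returns the singleton grid and perfect recall when separable", {
  set.seed(10)
  X <- rbind(matrix(rnorm(30 * 3, 0), ncol = 3), matrix(rnorm(60 * 3, 6), ncol = 3))
  colnames(X) <- paste0("f", 1:3)
  y <- c(rep("positive", 30), rep("negative", 60))
  grid <- hyperparameter_grid(adasyn_n_neighbors = 5, n_estimators = 50,
                              max_depth = 10, min_samples_split = 2,
                              min_samples_leaf = 1)
  best <- grid_search(X, y, grid, folds = 5, seed = 3)
  expect_identical(best$n_estimators, 50)
  expect_equal(max(attr(best, "search")$mean_recall), 1)
})

test_that("the final forest is seeded, normalized and finds planted signal", {
  set.seed(20)
  n <- 120
  signal <- c(rnorm(n / 2, 0), rnorm(n / 2, 4))
  X <- cbind(signal, matrix(rnorm(n * 20), ncol = 20))
  colnames(X) <- c("real", paste0("noise", 1:20))
  y <- rep(c("negative", "positive"), each = n / 2)
  params <- list(adasyn_n_neighbors = 5, n_estimators = 100, max_depth = 15,
                 min_samples_split = 2, min_samples_leaf = 1)
  m1 <- train_final_model(X, y, params, seed = 4)
  m2 <- train_final_model(X, y, params, seed = 4)
  expect_equal(m1$importances, m2$importances)
  expect_equal(sum(m1$importances$importance), 1, tolerance = 1e-9)
  top <- m1$importances$feature[which.max(m1$importances$importance)]
  expect_identical(top, "real")
  expect_gt(mean(scprio:::rf_prob(m1$forest, X[y == "positive", ])), 0.9)
})

test_that("cross-validated AUC matches the pairwise concordance oracle", {
  set.seed(30)
  for (i in 1:10) {
    n <- 40
    labels <- sample(c(rep("positive", 15), rep("negative", 25)))
    scores <- round(runif(n), 2) # ties likely
    sweep <- roc_sweep(labels, scores)
    expect_equal(attr(sweep, "auc"), auc_concordance(labels, scores),
                 tolerance = 1e-9)
  }

  # perfect scores give perfect metrics
  y <- rep(c("positive", "negative"), each = 30)
  X <- cbind(f1 = ifelse(y == "positive", 1, 0) + rnorm(60, 0, 0.01),
             f2 = rnorm(60))
  params <- list(adasyn_n_neighbors = 5, n_estimators = 60, max_depth = 10,
                 min_samples_split = 2, min_samples_leaf = 1)
  cv <- cross_validated_metrics(X, y, params, folds = 5, seed = 8)
  expect_equal(cv$auc, 1)
  expect_equal(cv$metrics$sensitivity, 1)
  expect_equal(cv$metrics$precision, 1)
  expect_identical(nrow(cv$oof), 60L)
})

test_that("the density-zero threshold behaves across regimes and is monotone in eps", {
  set.seed(40)
  neg <- pmin(rbeta(200, 2, 12), 0.3) # concentrated near 0.1, max 0.3
  thr <- density_zero_threshold(neg)
  expect_gt(thr, 0.3)
  expect_lt(thr, 0.6)

  unif <- runif(500)
  thr_u <- density_zero_threshold(unif)
  expect_equal(thr_u, unname(quantile(unif, 0.995)))

  expect_warning(thr_d <- density_zero_threshold(rep(0.2, 50)), regexp = "identical")
  expect_equal(thr_d, 0.201)

  t1 <- density_zero_threshold(neg, eps_frac = 1e-3)
  t2 <- density_zero_threshold(neg, eps_frac = 1e-2)
  expect_true(t2 <= t1)
})

test_that("prediction excludes training genes and respects the threshold", {
  genes <- paste0("g", 1:30)
  classes <- structure(list(positive = genes[1:5], negative = genes[6:10],
                            provenance = tibble::tibble()),
                       class = "training_classes")
  set.seed(50)
  fm <- tibble::tibble(gene = genes,
                       label = c(rep("positive", 5), rep("negative", 5),
                                 rep("unlabeled", 20)),
                       f1 = c(rep(1, 5), rep(0, 5), runif(20)),
                       f2 = runif(30))
  attr(fm, "groups") <- setNames(rep("sc_expression", 2), c("f1", "f2"))
  X <- as.matrix(fm[c("f1", "f2")])
  params <- list(adasyn_n_neighbors = 3, n_estimators = 50, max_depth = 5,
                 min_samples_split = 2, min_samples_leaf = 1)
  model <- suppressWarnings(train_final_model(X[1:10, ], fm$label[1:10], params, seed = 2))
  res <- predict_all(model, fm, classes, threshold = 0.5)
  expect_length(intersect(res$candidates$gene, c(classes$positive, classes$negative)), 0)
  expect_true(all(res$candidates$score > 0.5))
  expect_identical(res$candidates$gene,
                   res$candidates$gene[order(-res$candidates$score, res$candidates$gene)])

  res_high <- predict_all(model, fm, classes, threshold = 1)
  expect_identical(nrow(res_high$candidates), 0L)

  fm_bad <- fm; names(fm_bad)[3] <- "other"
  expect_error(predict_all(model, fm_bad, classes, 0.5),
               regexp = "other", class = "scprio_schema_error")
})

test_that("group importances aggregate sums and mean squares per block", {
  groups <- setNames(c(rep("sc_expression", 25), rep("trajectory", 25)),
                     paste0("f", 1:50))
  uniform <- tibble::tibble(feature = paste0("f", 1:50), importance = 1 / 50)
  gi <- group_importances(uniform, groups)
  expect_equal(gi$importance_sum, c(0.5, 0.5))
  expect_equal(gi$mean_square_x1000, rep(mean((1 / 50)^2) * 1000, 2))

  solo <- tibble::tibble(feature = "f1", importance = 1)
  gi2 <- group_importances(solo, groups)
  expect_equal(gi2$importance_sum, 1)

  expect_error(group_importances(tibble::tibble(feature = "zz", importance = 1), groups),
               class = "scprio_schema_error")
})
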