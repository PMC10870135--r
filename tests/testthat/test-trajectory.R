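test_that("precomputed pseudotime is min-max rescaled within cluster", {
  counts <- matrix(1, 3, 2, dimnames = list(NULL, c("g1", "g2")))
  am <- tiny_am(counts, clusters = rep("a", 3), pseudotime = c(2, 4, 6))
  pt <- assign_pseudotime(am, "precomputed")
  expect_equal(pt$pseudotime, c(0, 0.5, 1))
})

test_that("stage-rank pseudotime respects stage order, is unique and reproducible", {
  counts <- matrix(1, 40, 2, dimnames = list(NULL, c("g1", "g2")))
  set.seed(17)
  stages <- sample(rep(c("E9.5", "E10.5"), each = 20))
  am <- tiny_am(counts, clusters = rep("a", 40), stages = stages)
  pt1 <- assign_pseudotime(am, "stage_rank", seed = 3)
  pt2 <- assign_pseudotime(am, "stage_rank", seed = 3)
  expect_identical(pt1, pt2)
  early <- pt1$pseudotime[stages == "E9.5"]
  late <- pt1$pseudotime[stages == "E10.5"]
  expect_true(max(early) < min(late))
  expect_identical(anyDuplicated(pt1$pseudotime), 0L)
  expect_true(all(pt1$pseudotime >= 0 & pt1$pseudotime <= 1))

  am1 <- tiny_am(counts, clusters = rep("a", 40), stages = rep("E9.5", 40))
  expect_warning(assign_pseudotime(am1, "stage_rank"), regexp = "single stage")
})

test_that("binning pools equal-width intervals with the last bin closed", {
  set.seed(5)
  n <- 200
  ptime <- runif(n)
  expr <- matrix(c(rep(3, n), 2 * ptime), ncol = 2,
                 dimnames = list(NULL, c("const", "lin")))
  bins <- bin_expression(expr, ptime, n_bins = 20)
  const <- bins[bins$gene == "const", ]
  expect_true(all(abs(const$bin_mean - 3) < 1e-12))
  # interval-scan oracle for the linear gene
  lin <- bins[bins$gene == "lin", ]
  for (k in unique(lin$bin)) {
    inside <- ptime >= (k - 1) / 20 & (ptime < k / 20 | k == 20)
    expect_equal(lin$bin_mean[lin$bin == k], mean(2 * ptime[inside]), tolerance = 1e-12)
    expect_identical(lin$n_cells[lin$bin == k], as.integer(sum(inside)))
  }
  # boundary: pseudotime exactly 1 joins the last bin
  b <- bin_expression(matrix(5, 1, 1, dimnames = list(NULL, "g")), 1, n_bins = 20)
  expect_identical(b$bin, 20L)
  # empty bins are omitted
  b2 <- bin_expression(matrix(1:2, 2, 1, dimnames = list(NULL, "g")), c(0.01, 0.99),
                       n_bins = 20)
  expect_identical(nrow(b2), 2L)
})

test_that("clamped cubic basis has the expected knots and partition of unity", {
  basis <- build_basis(3, 10)
  expect_equal(basis$knots, c(rep(0, 4), (1:6) / 7, rep(1, 4)))
  B0 <- basis_matrix(basis, 0)
  expect_equal(as.numeric(B0), c(1, rep(0, 9)))
  grid <- seq(0, 1, length.out = 101)
  B <- basis_matrix(basis, grid)
  expect_true(all(abs(rowSums(B) - 1) <= 1e-12))
  expect_error(build_basis(3, 3), class = "scprio_param_error")
})

test_that("spline coefficients solve the ridge least-squares problem", {
  basis <- build_basis()
  # constant profile -> every coefficient equals the constant
  prof <- tibble::tibble(bin_center = (1:20 - 0.5) / 20, bin_mean = 2.5)
  beta <- fit_spline_coefficients(prof, basis)
  expect_true(all(abs(beta - 2.5) <= 1e-6))

  # random profile vs explicit normal-equations oracle
  set.seed(8)
  y <- rnorm(20)
  prof2 <- tibble::tibble(bin_center = (1:20 - 0.5) / 20, bin_mean = y)
  beta2 <- fit_spline_coefficients(prof2, basis, ridge = 1e-8)
  B <- basis_matrix(basis, prof2$bin_center)
  oracle <- solve(crossprod(B) + 1e-8 * diag(10), crossprod(B, y))
  expect_equal(beta2, as.numeric(oracle), tolerance = 1e-8)

  # single-bin profile stays finite (ridge regularized)
  beta3 <- fit_spline_coefficients(tibble::tibble(bin_center = 0.4, bin_mean = 1), basis)
  expect_true(all(is.finite(beta3)))
})

test_that("trajectory features have the right shape and reconstruct planted curves", {
  set.seed(77)
  n <- 240
  ptime <- runif(n)
  cl <- rep(c("a", "b"), each = n / 2)
  bump <- function(t) 4 * exp(-(t - 0.5)^2 / (2 * 0.1^2))
  counts <- cbind(
    planted = rpois(n, ifelse(cl == "a", 60 * bump(ptime) + 1, 1)),
    flat = rpois(n, 30),
    other = rpois(n, 5)
  )
  am <- tiny_am(counts, clusters = cl, pseudotime = ptime)
  am <- normalize_counts(am)
  tft <- trajectory_features(am, mode = "precomputed")
  expect_identical(dim(tft), c(3L * 2L, 2L + 10L))

  basis <- build_basis()
  beta <- as.numeric(tft[tft$gene == "planted" & tft$cluster == "a",
                         paste0("coef_", 0:9)])
  grid <- seq(0, 1, length.out = 101)
  fitted <- as.numeric(basis_matrix(basis, grid) %*% beta)
  # compare against the planted curve in normalized units via binned truth
  pt_a <- ptime[cl == "a"]
  expr_a <- as.matrix(am$norm[cl == "a", "planted", drop = FALSE])
  truth <- bin_expression(expr_a, pt_a)
  truth_interp <- approx(truth$bin_center, truth$bin_mean, xout = grid, rule = 2)$y
  r2 <- 1 - sum((fitted - truth_interp)^2) / sum((truth_interp - mean(truth_interp))^2)
  expect_gt(r2, 0.95)
})

test_that("trajectory features are cell-order invariant and pseudotime-affine invariant", {
  set.seed(12)
  n <- 80
  counts <- matrix(rpois(n * 4, 4), n, dimnames = list(NULL, paste0("g", 1:4)))
  counts[, 1] <- counts[, 1] + 1
  ptime <- runif(n)
  cl <- rep(c("a", "b"), each = n / 2)
  am <- normalize_counts(tiny_am(counts, cl, pseudotime = ptime))
  tft <- trajectory_features(am, mode = "precomputed")

  perm <- sample(n)
  amp <- normalize_counts(tiny_am(counts[perm, ], cl[perm], pseudotime = ptime[perm]))
  tftp <- trajectory_features(amp, mode = "precomputed")
  expect_equal(as.data.frame(dplyr::arrange(tft, cluster, gene)),
               as.data.frame(dplyr::arrange(tftp, cluster, gene)), tolerance = 1e-10)

  ama <- normalize_counts(tiny_am(counts, cl, pseudotime = 10 + 3 * ptime))
  tfta <- trajectory_features(ama, mode = "precomputed")
  expect_equal(as.data.frame(tft), as.data.frame(tfta), tolerance = 1e-10)
})

test_that("fits interpolate when bins equal basis dimension and constants never undershoot", {
  basis <- build_basis()
  set.seed(4)
  centers <- seq(0.05, 0.95, length.out = 10)
  y <- runif(10)
  beta <- fit_spline_coefficients(tibble::tibble(bin_center = centers, bin_mean = y),
                                  basis, ridge = 0)
  B <- basis_matrix(basis, centers)
  expect_lt(max(abs(B %*% beta - y)), 1e-8)

  const <- fit_spline_coefficients(
    tibble::tibble(bin_center = (1:20 - 0.5) / 20, bin_mean = 0.7), basis)
  curve <- basis_matrix(basis, seq(0, 1, length.out = 201)) %*% const
  expect_gt(min(curve), -1e-6)
})
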