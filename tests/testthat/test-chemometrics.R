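# Feature-table preprocessing, PCA, and data fusion.

small_fm <- function(seed = 3L, n_features = 120L) {
  gen_feature_table(n_features = n_features, seed = seed)
}

test_that("total-signal normalization gives unit row sums and is
           scale-invariant", {
  g <- small_fm()
  fm <- normalize_total_signal(g$matrix)
  expect_equal(unname(rowSums(fm$values)), rep(1, nrow(fm$values)))
  # two rows that are scaled copies become identical
  v <- g$matrix$values
  v[2, ] <- 3.7 * v[1, ]
  fm2 <- normalize_total_signal(feature_matrix(v, g$matrix$sample_info))
  expect_equal(fm2$values[1, ], fm2$values[2, ])
  # zero-sum rows are named
  v[5, ] <- 0
  expect_error(normalize_total_signal(feature_matrix(v, g$matrix$sample_info)),
               rownames(v)[5], fixed = TRUE)
})

test_that("pareto scaling: mean zero, variance = original sd", {
  g <- small_fm()
  raw_sd <- apply(g$matrix$values, 2, sd)
  fm <- pareto_scale(normalize_total_signal(g$matrix))
  expect_equal(unname(colMeans(fm$values)), rep(0, ncol(fm$values)),
               tolerance = 1e-12)
  norm_sd <- apply(normalize_total_signal(g$matrix)$values, 2, sd)
  expect_equal(unname(apply(fm$values, 2, var)), unname(norm_sd),
               tolerance = 1e-9)
  # the (1,2,3) column has sd 1, so sqrt(sd) = 1 leaves (-1, 0, 1)
  v <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2,
              dimnames = list(paste0("s", 1:3), c("a", "const")))
  fmc <- feature_matrix(v, data.frame(method = c("A", "B", "C")))
  expect_warning(sc <- pareto_scale(fmc), "constant")
  expect_equal(unname(sc$values[, "a"]), c(-1, 0, 1))
  expect_equal(unname(sc$values[, "const"]), c(0, 0, 0))
})

test_that("pipeline order is enforced", {
  g <- small_fm()
  fm <- pareto_scale(normalize_total_signal(g$matrix))
  expect_error(normalize_total_signal(fm), "raw")
  expect_error(pareto_scale(fm), "already")
  at <- data.frame(PV = 1, TPC = 1, RSA = 1, AUC = 1,
                   row.names = rownames(fm$values)[1])
  expect_error(fuse_variables(fm, at), "Pareto")
  expect_warning(pca(normalize_total_signal(g$matrix)), "Pareto")
})

test_that("pca: rank-1 variance, known covariance, exact reconstruction", {
  # rank-1 matrix explains everything on PC1
  u <- 1:6; w <- c(2, -1, 0.5)
  v <- outer(u, w)
  dimnames(v) <- list(paste0("s", 1:6), paste0("f", 1:3))
  fm <- feature_matrix(abs(v), data.frame(method = rep(c("A", "B"), 3)))
  fm$values <- sweep(v, 2, colMeans(v))  # bypass scaling, column-center
  fm$scaling_state <- "pareto"
  m <- pca(fm, 1)
  expect_equal(m$r2x[1], 1, tolerance = 1e-9)

  # 2-feature Gaussian cloud with eigenvalues (9, 1)
  X <- withr::with_seed(42L,
    cbind(rnorm(500, sd = 3), rnorm(500, sd = 1)))
  dimnames(X) <- list(paste0("s", 1:500), c("f1", "f2"))
  fm2 <- feature_matrix(X - min(X), data.frame(method = rep("A", 500)))
  fm2$values <- scale(fm2$values, center = TRUE, scale = FALSE)
  fm2$scaling_state <- "pareto"
  m2 <- pca(fm2, 2)
  expect_equal(m2$r2x, c(0.9, 0.1), tolerance = 0.03 / 0.9)
  expect_true(all(diff(m2$r2x) <= 0))
  expect_equal(crossprod(m2$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # full-rank reconstruction
  g <- small_fm()
  fm3 <- pareto_scale(normalize_total_signal(g$matrix))
  k <- min(nrow(fm3$values) - 1L, ncol(fm3$values))
  m3 <- pca(fm3, k)
  expect_lt(max(abs(m3$scores %*% t(m3$loadings) - fm3$values)), 1e-9)
  expect_error(pca(fm3, k + 1), "n_components")
})

test_that("fusion appends the assay block and reverts exactly", {
  g <- small_fm()
  fm <- normalize_total_signal(g$matrix)
  ids <- rownames(fm$values)
  at <- data.frame(PV = runif(length(ids), 90, 130),
                   TPC = runif(length(ids), 0.3, 14),
                   RSA = runif(length(ids), 0.4, 8),
                   AUC = runif(length(ids), 9e6, 1.5e8),
                   row.names = ids)
  fused <- fuse_variables(fm, at)
  expect_equal(ncol(fused$values), ncol(fm$values) + 4L)
  expect_identical(unfuse_variables(fused)$values, fm$values)
  expect_error(fuse_variables(fm, at[-1, , drop = FALSE]), ids[1], fixed = TRUE)
})

test_that("fused PCA puts AUC and TPC loadings on opposite signs of PC1
           when assay values follow the per-method pattern", {
  g <- gen_feature_table(n_features = 400L, seed = 21L)
  fm <- normalize_total_signal(g$matrix)
  fx <- fixtures_table1()
  info <- fm$sample_info
  at <- data.frame(PV = vapply(info$method, function(m) fx[[m]]$PV, 1),
                   TPC = vapply(info$method, function(m) fx[[m]]$TPC, 1),
                   RSA = vapply(info$method, function(m) fx[[m]]$RSA, 1),
                   AUC = vapply(info$method, function(m) fx[[m]]$AUC_measured, 1),
                   row.names = rownames(fm$values))
  m <- pca(pareto_scale(fuse_variables(fm, at)), 2)
  # TPC tracks the solvent-polarity axis, AUC opposes it
  expect_lt(m$loadings["AUC", 1] * m$loadings["TPC", 1], 0)
})

test_that("the default generator separates extraction methods in score
           space (mean silhouette > 0.5)", {
  g <- gen_feature_table(seed = 5L)  # full 1650-feature default table
  fm <- pareto_scale(normalize_total_signal(g$matrix))
  m <- pca(fm, 2)
  expect_gt(mean_silhouette(fm$sample_info$method, m$scores), 0.5)
})

test_that("effect = 0 gives no group structure", {
  g <- gen_feature_table(n_features = 300L, effect = 0, seed = 9L)
  fm <- pareto_scale(normalize_total_signal(g$matrix))
  m <- pca(fm, 2)
  expect_lt(mean_silhouette(fm$sample_info$method, m$scores), 0.25)
})
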