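make_scores_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  d <- ncol(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    matrix(stats::rnorm(n_per * d, sd = sd), ncol = d) +
      matrix(centers[g, ], n_per, d, byrow = TRUE)
  }))
  list(scores = X,
       labels = rep(sprintf("G%d", seq_len(nrow(centers))), each = n_per))
}

test_that("centering imputes the variant mean and centers columns", {
  ds <- make_chrom_dataset(list(c(0L, 1L), c(1L, NA), c(2L, 2L)),
                           pos = c(1e5, 2e5))
  ctr <- center_matrix(ds)
  expect_equal(unname(ctr$X[, 1]), c(-1, 0, 1))
  expect_equal(unname(ctr$X[, 2]), c(-0.5, 0, 0.5))
  expect_equal(unname(ctr$variant_means), c(1, 1.5))
  expect_true(all(abs(colMeans(ctr$X)) < 1e-12))

  ds_bad <- make_chrom_dataset(list(c(NA_integer_, 0L),
                                    c(NA_integer_, 1L)),
                               pos = c(1e5, 2e5))
  expect_error(center_matrix(ds_bad), "all-missing")
})

test_that("pca matches a dense eigendecomposition and reconstructs", {
  set.seed(8)
  X <- matrix(stats::rnorm(50 * 200), nrow = 50)
  X <- sweep(X, 2, colMeans(X))
  b <- pca(X, 20)
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(b$eigenvalues, ev[1:20], tolerance = 1e-8)

  full <- pca(X, 50)
  expect_equal(full$scores %*% t(full$loadings), X, tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 matrix: first component carries all variance
  X1 <- outer(stats::rnorm(30), stats::rnorm(40))
  X1 <- sweep(X1, 2, colMeans(X1))
  b1 <- pca(X1, 5)
  expect_equal(b1$eigenvalues[1] / b1$total_variance, 1,
               tolerance = 1e-10)
  expect_error(pca(X, 60), "exceeds")
})

test_that("BIC scan recovers blob counts and reports coherent deltas", {
  # dimension high enough that the K log(n) penalty dominates chance
  # splits of a single Gaussian (see the methods vignette)
  d <- 100
  # centers 10x the blob spread (sqrt(d)) apart
  two <- make_scores_blobs(100, rbind(rep(0, d), rep(10, d)), seed = 2)
  scan2 <- kmeans_bic_scan(two$scores, k_max = 8, seed = 5)
  expect_equal(scan2$k_best, 2L)

  one <- make_scores_blobs(200, matrix(0, 1, d), seed = 3)
  scan1 <- kmeans_bic_scan(one$scores, k_max = 8, seed = 5)
  expect_equal(scan1$k_best, 1L)

  # WSS non-increasing, BIC/delta arithmetic coherent
  expect_true(all(diff(scan1$scan$wss) <= 1e-8))
  expect_true(all(diff(scan2$scan$wss) <= 1e-8))
  n <- nrow(two$scores)
  expect_equal(scan2$scan$bic,
               n * log(scan2$scan$wss / n) + scan2$scan$k * log(n))
  k_max <- nrow(scan2$scan)
  expect_equal(scan2$scan$delta_bic[-k_max],
               scan2$scan$bic[-k_max] - scan2$scan$bic[-1])

  # determinism
  scan2b <- kmeans_bic_scan(two$scores, k_max = 8, seed = 5)
  expect_identical(scan2$scan, scan2b$scan)
})

test_that("DAPC matches the generalized-eigenproblem oracle", {
  fx <- make_scores_blobs(8, matrix(stats::rnorm(3 * 6, sd = 2),
                                    nrow = 3), seed = 12)
  fit <- dapc_fit(fx$scores, fx$labels)
  # oracle: eigen of solve(W) %*% B with the same scalings
  labels <- factor(fx$labels)
  X <- fx$scores
  M <- do.call(rbind, lapply(levels(labels), function(g)
    colMeans(X[labels == g, , drop = FALSE])))
  W <- crossprod(X - M[as.integer(labels), ]) / (nrow(X) - 3)
  ng <- as.numeric(table(labels))
  Mc <- sweep(M, 2, colMeans(X), "-")
  B <- crossprod(Mc * sqrt(ng)) / 2
  ev <- eigen(solve(W) %*% B)
  expect_equal(fit$eigenvalues, Re(ev$values[1:2]), tolerance = 1e-8)
  # axes span the same subspace (compare via projection correlation)
  for (k in 1:2) {
    a <- fit$axes[, k]
    o <- Re(ev$vectors[, k])
    expect_gt(abs(stats::cor(a, o)), 1 - 1e-6)
  }
  # axes are within-covariance orthonormal
  expect_equal(t(fit$axes) %*% W %*% fit$axes, diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("DAPC degenerate and separable cases behave", {
  set.seed(4)
  base <- matrix(stats::rnorm(40 * 5), nrow = 40)
  same_means <- rbind(base, base)  # two groups, identical means
  fit0 <- dapc_fit(same_means, rep(c("a", "b"), each = 40))
  expect_lt(fit0$eigenvalues[1], 1e-8)

  sep <- make_scores_blobs(20, rbind(rep(0, 5), rep(50, 5)), seed = 6)
  fit1 <- dapc_fit(sep$scores, sep$labels)
  pred <- dapc_predict(fit1, sep$scores)
  expect_equal(mean(as.character(pred$assigned) == sep$labels), 1)
  expect_equal(unname(rowSums(pred$posterior)), rep(1, 40),
               tolerance = 1e-9)
})

test_that("DAPC agrees with an independent LDA on full rank", {
  skip_if_not_installed("MASS")
  fx <- make_scores_blobs(30, matrix(stats::rnorm(3 * 8), nrow = 3),
                          seed = 21)
  fit <- dapc_fit(fx$scores, fx$labels)
  pred <- dapc_predict(fit, fx$scores)
  ld <- MASS::lda(fx$scores, grouping = fx$labels)
  pl <- stats::predict(ld, fx$scores)
  expect_equal(as.character(pred$assigned), as.character(pl$class))
  expect_equal(unname(pred$posterior),
               unname(pl$posterior[, fit$group_labels]),
               tolerance = 1e-6)
})

test_that("DAPC is invariant to group relabeling", {
  fx <- make_scores_blobs(15, matrix(stats::rnorm(3 * 6), nrow = 3),
                          seed = 31)
  f1 <- dapc_fit(fx$scores, factor(fx$labels,
                                   levels = c("G1", "G2", "G3")))
  f2 <- dapc_fit(fx$scores, factor(fx$labels,
                                   levels = c("G3", "G1", "G2")))
  p1 <- dapc_predict(f1, fx$scores)$posterior
  p2 <- dapc_predict(f2, fx$scores)$posterior
  expect_equal(p1[, c("G1", "G2", "G3")], p2[, c("G1", "G2", "G3")],
               tolerance = 1e-9)
})

test_that("raw-genotype prediction centers with the model means", {
  sim <- simulate_subpopulations(
    sim_params(n_pops = 2, n_per_pop = 25, n_snps = 400, fst = 0.15,
               missing_rate = 0.02, seed = 14))
  ds <- sim$dataset
  ctr <- center_matrix(ds)
  basis <- pca(ctr, 10)
  fit <- dapc_fit(basis, ds$samples$subgroup, n_pcs = 10)
  via_scores <- dapc_predict(fit, basis$scores)
  via_raw <- dapc_predict(fit, ds)
  expect_equal(via_raw$posterior, via_scores$posterior,
               tolerance = 1e-9, ignore_attr = TRUE)

  other <- subset_dataset(ds, variants = 1:100)
  expect_error(dapc_predict(fit, other), "lacks model variants")
})

test_that("reassignment accuracy aggregates correctly", {
  labels <- rep(c("AS", "DM", "GP", "PR", "TR"), each = 200)
  assigned <- labels
  set.seed(2)
  flip <- sample(1000, 239)
  for (i in flip) assigned[i] <- sample(setdiff(unique(labels),
                                                labels[i]), 1)
  acc <- reassignment_accuracy(assigned, labels)
  expect_equal(acc$overall, 0.761)
  w <- sum(acc$by_group$accuracy * acc$by_group$n) /
    sum(acc$by_group$n)
  expect_equal(w, acc$overall)
  expect_equal(reassignment_accuracy(labels, labels)$overall, 1)
})

test_that("PC-retention cross-validation is deterministic and finds
          the separable optimum", {
  fx <- make_scores_blobs(20, matrix(c(0, 0, 0, 8, 0, 0, 0, 8, 0,
                                       4, 4, 4), nrow = 4,
                                     byrow = TRUE), seed = 41)
  noise <- matrix(stats::rnorm(80 * 17, sd = 3), nrow = 80)
  scores <- cbind(fx$scores, noise)
  xv <- xval_select_npcs(scores, fx$labels, npc_grid = c(2, 3, 10, 20),
                         reps = 8, seed = 9)
  expect_equal(xv$rmse$rmse[xv$rmse$n_pcs == xv$chosen_npcs],
               min(xv$rmse$rmse))
  xv2 <- xval_select_npcs(scores, fx$labels, npc_grid = c(2, 3, 10, 20),
                          reps = 8, seed = 9)
  expect_identical(xv$results, xv2$results)
  expect_identical(xv$chosen_npcs, xv2$chosen_npcs)

  # a perfect classifier at some n_pcs gives RMSE 0 there
  sep <- make_scores_blobs(20, rbind(rep(0, 4), rep(60, 4)), seed = 44)
  xvs <- xval_select_npcs(sep$scores, sep$labels, npc_grid = c(2, 4),
                          reps = 5, seed = 3)
  expect_equal(min(xvs$rmse$rmse), 0)
})

test_that("pairwise external validation: reproducible, null near chance,
          strong divergence near ceiling", {
  simd <- simulate_subpopulations(
    sim_params(n_pops = 2, n_per_pop = 40, n_snps = 500, fst = 0.15,
               missing_rate = 0, genotype_error_rate = 0, seed = 51))
  pv <- pairwise_external_validation(simd$dataset, c("P01", "P02"),
                                     n_pcs = 20, seed = 7)
  expect_gte(pv$mean, 0.9)
  pv2 <- pairwise_external_validation(simd$dataset, c("P01", "P02"),
                                      n_pcs = 20, seed = 7)
  expect_identical(pv$per_rep_accuracy, pv2$per_rep_accuracy)

  sim0 <- simulate_subpopulations(
    sim_params(n_pops = 2, n_per_pop = 40, n_snps = 500, fst = 0,
               missing_rate = 0, genotype_error_rate = 0, seed = 52))
  pv0 <- pairwise_external_validation(sim0$dataset, c("P01", "P02"),
                                      n_pcs = 20, seed = 8)
  expect_gt(pv0$mean, 0.25)
  expect_lt(pv0$mean, 0.75)
})

test_that("tidy/glance/autoplot methods return well-formed objects", {
  fx <- make_scores_blobs(15, matrix(stats::rnorm(2 * 5), nrow = 2),
                          seed = 61)
  scan <- kmeans_bic_scan(fx$scores, k_max = 5, seed = 1)
  td <- tidy(scan)
  expect_true(all(c("k", "wss", "bic", "delta_bic") %in% names(td)))
  expect_s3_class(glance(scan), "tbl_df")
  expect_s3_class(autoplot(scan), "ggplot")

  fit <- dapc_fit(fx$scores, fx$labels)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_groups, 2)
  expect_s3_class(autoplot(fit), "ggplot")

  pred <- dapc_predict(fit, fx$scores)
  expect_s3_class(tidy(pred), "tbl_df")
})
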