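test_that("Pareto scaling centres columns and damps by sqrt(sd)", {
  m <- matrix(c(1, 3, 5, 5), nrow = 2,
              dimnames = list(c("s1", "s2"), c("F1", "F2")))
  sc <- pareto_scale(m)
  # (1,3): mean 2, sample sd sqrt(2) -> +/- 1/2^(1/4)
  expect_equal(unname(sc[, "F1"]), c(-0.8409, 0.8409), tolerance = 1e-4)
  expect_equal(unname(sc[, "F2"]), c(0, 0))
  expect_true(attr(sc, "zero_variance")[["F2"]])
  expect_equal(max(abs(colMeans(sc))), 0, tolerance = 1e-12)
  expect_error(pareto_scale(m[1, , drop = FALSE]), "2 samples")
})

test_that("half-minimum imputation fills zeros and NAs", {
  m <- matrix(c(0, 4, NA, 8), 2, 2)
  out <- impute_halfmin(m)
  expect_equal(out[1, 1], 2)
  expect_equal(out[1, 2], 2)
  expect_equal(out[2, ], c(4, 8))
})

test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(12), 4, 3)
  pca <- fit_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)
  k <- length(pca$eigenvalues)
  expect_equal(pca$eigenvalues, ev$values[seq_len(k)], tolerance = 1e-8)
  for (a in seq_len(ncol(pca$loadings))) {
    expect_equal(abs(sum(pca$loadings[, a] * ev$vectors[, a])), 1,
                 tolerance = 1e-8)
  }
  # scores are the centred data projected on the loadings
  xc <- sweep(x, 2, colMeans(x), "-")
  expect_equal(unname(pca$scores), unname(xc %*% pca$loadings),
               tolerance = 1e-8)
  expect_equal(sum(pca$full_variance_pct), 100, tolerance = 1e-6)
  # score columns are mutually orthogonal
  g <- crossprod(pca$scores)
  expect_equal(unname(g[upper.tri(g)]), rep(0, sum(upper.tri(g))),
               tolerance = 1e-8)
})

test_that("rank-1 data loads entirely on the first component", {
  u <- c(-1, 0, 2, 3); v <- c(1, 2, 3)
  x <- outer(u, v)
  pca <- fit_pca(x, 1)
  expect_equal(pca$explained_variance_pct[1], 100, tolerance = 1e-9)
  expect_equal(pca$r2_cum[1], 1, tolerance = 1e-9)
  expect_error(fit_pca(matrix(5, 3, 3)), "constant")
  expect_error(fit_pca(x, 10), "n_components")
})

test_that("Q2 is high for predictable structure and low for noise", {
  set.seed(7)
  u <- rnorm(8); v <- rnorm(40)
  rank1 <- (u - mean(u)) %*% t(v)
  expect_gte(q2_crossval(rank1, 1)[1], 0.99)

  noise <- matrix(rnorm(8 * 40), 8, 40)
  expect_lte(max(q2_crossval(noise, 3)), 0.5)

  # Q2 <= R2 on every tested matrix
  for (s in 1:3) {
    set.seed(s)
    x <- matrix(rnorm(7 * 15), 7, 15)
    q2 <- q2_crossval(x, 3)
    r2 <- fit_pca(x, 3)$r2_cum
    expect_true(all(q2 <= r2 + 1e-8))
  }
  expect_error(q2_crossval(noise[1:2, ]), "3 samples")
  expect_error(q2_crossval(noise, 50), "rank")
})

test_that("PLS-DA weights match an independent NIPALS oracle", {
  set.seed(3)
  x <- matrix(rnorm(6 * 4), 6, 4)
  labels <- rep(c("a", "b"), each = 3)
  model <- fit_plsda(x, labels, 2)
  expect_equal(unname(model$weights[, 1]),
               unname(nipals_first_weights(x, labels)), tolerance = 1e-6)
  expect_error(fit_plsda(x, rep("a", 6)), "2 distinct classes")
  expect_error(fit_plsda(x, labels, 10), "samples - 1")
  expect_warning(fit_plsda(x, c("a", "a", "a", "a", "a", "b"), 1),
                 "single sample")
})

test_that("PLS-DA agrees with mixOmics on an unscaled fit", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  x <- matrix(rnorm(6 * 8), 6, 8)
  labels <- rep(c("a", "b"), each = 3)
  model <- fit_plsda(x, labels, 2)
  mo <- mixOmics::plsda(x, factor(labels), ncomp = 2, scale = FALSE)
  for (k in 1:2) {
    w <- model$weights[, k]; m <- mo$loadings$X[, k]
    cosine <- abs(sum(w * m)) / sqrt(sum(w^2) * sum(m^2))
    expect_equal(cosine, 1, tolerance = 1e-6)
  }
})

test_that("cumulative fitted variance is non-decreasing in components", {
  set.seed(14)
  x <- matrix(rnorm(10 * 20), 10, 20)
  labels <- rep(c("a", "b"), each = 5)
  model <- fit_plsda(x, labels, 4)
  expect_true(all(model$explained_variance_pct > 0))
  expect_true(all(diff(cumsum(model$explained_variance_pct)) > 0))
})

test_that("sparsity keeps only the strongest weights per component", {
  sim <- simulate_intensity_matrix(n_groups = 2, n_per_group = 4,
                                   n_features = 30, n_discriminant = 1,
                                   effect_size = 5, seed = 6)
  sc <- pareto_scale(sim$matrix)
  sparse <- fit_plsda(sc, sim$labels, 1, keep_per_component = 3)
  expect_length(sparse$selected_features[[1]], 3L)
  expect_true(sim$truth$feature_id %in% sparse$selected_features[[1]])
  expect_equal(sum(sparse$weights[, 1] != 0), 3L)
})

test_that("VIP normalisation and single-component closed form hold", {
  set.seed(9)
  x <- matrix(rnorm(8 * 2), 8, 2)
  labels <- rep(c("a", "b"), each = 4)
  model <- fit_plsda(x, labels, 1)
  vip <- vip_scores(model)
  # one component: VIP_j reduces to sqrt(p) * |w_j|
  expect_equal(unname(vip), sqrt(2) * abs(unname(model$weights[, 1])),
               tolerance = 1e-8)
  expect_equal(mean(vip^2), 1, tolerance = 1e-9)

  sim <- simulate_intensity_matrix(n_groups = 2, n_per_group = 3,
                                   n_features = 6, n_discriminant = 1,
                                   effect_size = 5, seed = 4)
  v2 <- vip_scores(fit_plsda(pareto_scale(sim$matrix), sim$labels, 2))
  expect_equal(mean(v2^2), 1, tolerance = 1e-9)
  expect_equal(names(which.max(v2)), sim$truth$feature_id)
})

test_that("clustering reproduces hand-traced merges on a 3-4-5 triangle", {
  x <- rbind(A = c(0, 0), B = c(3, 0), C = c(0, 4))
  single <- hca(x, linkage = "single")
  expect_equal(single$height, c(3, 4))
  expect_equal(single$merge[1, ], c(-1, -2)) # A-B merge first at 3
  avg <- hca(x, linkage = "average")
  expect_equal(avg$height, c(3, 4.5))

  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  tree <- hca(dup, linkage = "average")
  expect_equal(tree$height[1], 0)

  bad <- x; bad[1, 1] <- NaN
  expect_error(hca(bad), "non-finite")
  expect_error(hca(x[1, , drop = FALSE]), "2 rows")
})

test_that("newick export preserves the leaf set", {
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  nwk <- hca_to_newick(hca(x))
  expect_match(nwk, "^\\(")
  for (s in rownames(x)) expect_match(nwk, s, fixed = TRUE)
})

test_that("ANOVA ranking matches t-tests and recovers planted effects", {
  set.seed(33)
  # two groups: F must equal the squared pooled t statistic
  x <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(NULL, paste0("F", 1:5)))
  g <- rep(c("a", "b"), each = 4)
  top <- top_features_anova(x, g, 5)
  for (j in seq_len(5)) {
    tt <- t.test(x[, paste0("F", j)] ~ g, var.equal = TRUE)
    row <- top[top$feature_id == paste0("F", j), ]
    expect_equal(row$f_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-8)
  }
  expect_equal(nrow(top_features_anova(x, g, 100)), 5L)
  expect_error(top_features_anova(x, g, 0), "positive")

  # planted additive 5-sigma shift ranks first
  x2 <- matrix(rnorm(10 * 50), 10, 50)
  g2 <- rep(c("a", "b"), each = 5)
  x2[g2 == "b", 7] <- x2[g2 == "b", 7] + 5
  expect_equal(top_features_anova(x2, g2, 1)$feature_id, "F7")

  # log-scale ANOVA on the generator recovers its planted feature
  sim <- simulate_intensity_matrix(n_discriminant = 1, effect_size = 5,
                                   seed = 2)
  ta <- top_features_anova(log(as.matrix(sim$matrix)), sim$labels, 1)
  expect_equal(ta$feature_id, sim$truth$feature_id)

  expect_warning(
    fb <- top_features_anova(x, c(rep("a", 7), "b"), 3),
    "variance ranking"
  )
  expect_equal(nrow(fb), 3L)
})

test_that("Fisher LSD post hoc context is attached but not used to rank", {
  set.seed(44)
  x <- matrix(rnorm(9 * 4), 9, 4)
  g <- rep(c("a", "b", "c"), each = 3)
  top <- top_features_anova(x, g, 2, posthoc = TRUE)
  expect_true(all(vapply(top$lsd, is.matrix, logical(1))))
  expect_equal(dim(top$lsd[[1]]), c(2L, 2L))
})

test_that("heatmap data is restricted, z-scored and block-ordered", {
  sim <- simulate_intensity_matrix(n_groups = 2, n_per_group = 4,
                                   n_features = 40, n_discriminant = 6,
                                   effect_size = 4, seed = 13)
  hm <- heatmap_data(log(as.matrix(sim$matrix)), sim$labels, n_top = 10)
  expect_equal(nrow(hm$values), 10L)
  expect_equal(ncol(hm$values), 8L)
  # per-feature z-scoring: rows have mean ~0, sd ~1
  expect_equal(unname(rowMeans(hm$values)), rep(0, 10), tolerance = 1e-10)
  # samples of the same group cluster into contiguous column blocks
  grp <- sim$labels[match(hm$sample_order, rownames(as.matrix(sim$matrix)))]
  expect_equal(length(rle(grp)$lengths), 2L)
  # n_top larger than the feature count keeps everything
  hm_all <- heatmap_data(log(as.matrix(sim$matrix)), sim$labels, n_top = 99)
  expect_equal(nrow(hm_all$values), 40L)
})
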