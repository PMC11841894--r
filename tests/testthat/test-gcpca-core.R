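test_that("shared basis has orthonormal columns and correct rank", {
  pr <- random_pair(50, 5, seed = 21)
  sb <- build_shared_basis(preprocess_pair_for_test(pr))
  expect_equal(sb$rank_k, 5)
  expect_equal(crossprod(sb$basis_j), diag(5), tolerance = 1e-10)

  # rank-2 data: both conditions copies of the same rank-2 matrix
  set.seed(22)
  low <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 6), 2, 6)
  pr2 <- condition_pair(low, low)
  expect_equal(build_shared_basis(pr2)$rank_k, 2)

  # p > n: rank bounded by the centered sample count
  pr3 <- random_pair(30, 100, seed = 23)
  ctr <- condition_pair(center_features(pr3$a), center_features(pr3$b))
  expect_lte(build_shared_basis(ctr)$rank_k, 60)

  expect_error(build_shared_basis(condition_pair(matrix(0, 4, 3),
                                                 matrix(0, 4, 3))),
               "all-zero")
})

test_that("symmetric_sqrt reconstructs and rejects non-PD input", {
  expect_equal(symmetric_sqrt(diag(2)), diag(2), ignore_attr = TRUE)
  expect_equal(symmetric_sqrt(diag(c(4, 9))), diag(c(2, 3)),
               ignore_attr = TRUE)
  set.seed(24)
  g <- matrix(rnorm(16), 4)
  s <- crossprod(g) + diag(4)
  m <- symmetric_sqrt(s)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(m %*% m, s, tolerance = 1e-10)
  expect_equal(attr(m, "inverse") %*% m, diag(4), tolerance = 1e-10)
  expect_error(symmetric_sqrt(diag(c(1, -1))), "positive definite")
})

test_that("diagonal covariances give the closed-form symmetric index", {
  pr <- diagonal_pair(var_a = c(4, 1), var_b = c(1, 1))
  fit <- fit_gcpca(pr, "v4")
  expect_equal(fit$eigenvalues, c(0.6, 0), tolerance = 1e-9)
  expect_equal(abs(fit$loadings[, 1]), c(1, 0), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("identical conditions give an all-zero v4 spectrum", {
  set.seed(25)
  x <- matrix(rnorm(120), 30, 4)
  fit <- fit_gcpca(condition_pair(x, x), "v4")
  expect_equal(fit$eigenvalues, rep(0, 4), tolerance = 1e-10)
})

test_that("v2/v3/v4 match the dense generalized-eigendecomposition oracle", {
  for (seed in 1:6) {
    p <- sample(3:6, 1)
    pr <- random_pair(n = 50, p = p, seed = 100 + seed,
                      scale_a = seq(2, 1, length.out = p))
    ca <- compute_covariance(center_features(pr$a))
    cb <- compute_covariance(center_features(pr$b))
    for (v in c("v2", "v3", "v4")) {
      num <- if (v == "v2") ca else ca - cb
      den <- if (v == "v4") ca + cb else cb
      oracle <- generalized_eigen_oracle(num, den)
      fit <- fit_gcpca(pr, v)
      expect_equal(fit$eigenvalues, oracle$values, tolerance = 1e-8)
      # same one-dimensional eigenspaces, up to sign, away from ties
      gaps <- c(Inf, abs(diff(oracle$values)), Inf)
      for (i in seq_len(p)) {
        if (min(gaps[i], gaps[i + 1]) > 1e-6) {
          expect_equal(abs(sum(fit$loadings[, i] * oracle$vectors[, i])), 1,
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("eigenvalue bounds hold over 100 random instances", {
  worst_v4 <- 0; worst_v3 <- Inf; worst_v2 <- Inf
  for (seed in 1:100) {
    pr <- random_pair(n = 20, p = 5, seed = 1000 + seed)
    worst_v4 <- max(worst_v4, abs(fit_gcpca(pr, "v4")$eigenvalues))
    worst_v3 <- min(worst_v3, fit_gcpca(pr, "v3")$eigenvalues)
    worst_v2 <- min(worst_v2, fit_gcpca(pr, "v2")$eigenvalues)
  }
  expect_lte(worst_v4, 1 + 1e-9)
  expect_gte(worst_v3, -1 - 1e-9)
  expect_gte(worst_v2, -1e-9)
})

test_that("v4 is antisymmetric in the two conditions", {
  for (seed in 1:5) {
    pr <- random_pair(n = 30, p = 4, seed = 200 + seed)
    fwd <- fit_gcpca(pr, "v4")
    bwd <- fit_gcpca(condition_pair(pr$b, pr$a), "v4")
    expect_equal(fwd$eigenvalues, -rev(bwd$eigenvalues), tolerance = 1e-9)
  }
})

test_that("v2/v3/v4 eigenvalues are invariant to a global rescaling", {
  pr <- random_pair(40, 4, seed = 31)
  scaled <- condition_pair(pr$a * 7.3, pr$b * 7.3)
  for (v in c("v2", "v3", "v4")) {
    expect_equal(fit_gcpca(scaled, v)$eigenvalues,
                 fit_gcpca(pr, v)$eigenvalues, tolerance = 1e-9)
  }
})

test_that("model contracts: unit loadings, orthonormal Y, sorted spectrum", {
  pr <- random_pair(60, 6, seed = 32, scale_a = seq(3, 1, length.out = 6))
  fit <- fit_gcpca(pr, "v4")
  expect_equal(sqrt(colSums(fit$loadings^2)), rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(fit$components_y), diag(6), tolerance = 1e-10)
  expect_equal(fit$eigenvalues, sort(fit$eigenvalues, decreasing = TRUE))
  # sign convention: largest-magnitude entry positive
  for (i in 1:6) {
    col <- fit$loadings[, i]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("transform projects data onto the loadings", {
  pr <- random_pair(30, 4, seed = 33)
  fit <- fit_gcpca(pr, "v4")
  expect_equal(as.matrix(gcpca_transform(fit, matrix(0, 2, 4))),
               matrix(0, 2, 4), ignore_attr = TRUE)
  onehot <- diag(4)[2, , drop = FALSE]
  expect_equal(unlist(gcpca_transform(fit, onehot)), fit$loadings[2, ],
               ignore_attr = TRUE)
  expect_error(gcpca_transform(fit, matrix(0, 2, 3)), "features")

  # v2 eigenvalues are the per-component variance ratios of the scores
  pr2 <- random_pair(200, 4, seed = 34, scale_a = c(3, 2, 1, 1))
  fit2 <- fit_gcpca(pr2, "v2")
  sa <- as.matrix(gcpca_transform(fit2, center_features(pr2$a)))
  sb <- as.matrix(gcpca_transform(fit2, center_features(pr2$b)))
  ratio <- colSums(sa^2) / (nrow(sa) - 1) / (colSums(sb^2) / (nrow(sb) - 1))
  expect_equal(unname(ratio), fit2$eigenvalues, tolerance = 1e-8)
})
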