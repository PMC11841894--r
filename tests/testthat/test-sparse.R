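test_that("build_theta matches the diagonal closed form and v4 bounds", {
  # identical conditions: zero target
  set.seed(61)
  x <- matrix(rnorm(200), 50, 4)
  pr <- condition_pair(x, x)
  prc <- preprocess_pair_for_test(pr)
  ca <- compute_covariance(prc$a); cb <- compute_covariance(prc$b)
  sb <- build_shared_basis(prc)
  np <- gcpca:::normalized_problem(sb$basis_j, ca - cb, ca + cb)
  expect_equal(build_theta(gcpca_variant("v4"), problem = np),
               matrix(0, np$rank_k, np$rank_k), tolerance = 1e-10)

  # diagonal instance: theta = diag((4-1)/(4+1), 0)
  prd <- diagonal_pair(var_a = c(4, 1), var_b = c(1, 1))
  cad <- compute_covariance(prd$a); cbd <- compute_covariance(prd$b)
  sbd <- build_shared_basis(prd)
  npd <- gcpca:::normalized_problem(sbd$basis_j, cad - cbd, cad + cbd)
  th <- build_theta(gcpca_variant("v4"), problem = npd)
  expect_equal(sort(diag(th), decreasing = TRUE), c(0.6, 0), tolerance = 1e-9)
  expect_equal(th[1, 2], 0, tolerance = 1e-9)

  # v3/v4 targets are bounded below by -1 on random instances
  min_ev <- Inf
  for (seed in 1:20) {
    pri <- preprocess_pair_for_test(random_pair(20, 5, seed = 600 + seed))
    cai <- compute_covariance(pri$a); cbi <- compute_covariance(pri$b)
    sbi <- build_shared_basis(pri)
    for (v in c("v3", "v4")) {
      den <- if (v == "v4") cai + cbi else cbi
      npi <- gcpca:::normalized_problem(sbi$basis_j, cai - cbi, den)
      ev <- eigen(build_theta(gcpca_variant(v), problem = npi),
                  symmetric = TRUE, only.values = TRUE)$values
      min_ev <- min(min_ev, ev)
      if (v == "v4") expect_lte(max(ev), 1 + 1e-9)
    }
  }
  expect_gte(min_ev, -1 - 1e-9)
})

test_that("tikhonov_repair shifts without reordering eigenvectors", {
  expect_equal(tikhonov_repair(diag(2)), diag(2))
  expect_equal(tikhonov_repair(diag(c(0.5, -0.5)), epsilon = 0.01),
               diag(c(1.01, 0.01)))
  set.seed(62)
  g <- matrix(rnorm(25), 5)
  th <- (g + t(g)) / 2
  rep_th <- tikhonov_repair(th)
  e0 <- eigen(th, symmetric = TRUE)
  e1 <- eigen(rep_th, symmetric = TRUE)
  expect_gt(min(e1$values), 0)
  expect_equal(abs(colSums(e0$vectors * e1$vectors)), rep(1, 5),
               tolerance = 1e-9)
  expect_equal(order(e0$values), order(e1$values))
})

test_that("elastic-net step satisfies the subgradient optimality conditions", {
  # KKT certificate for f(w) = ||r - Zw||^2 + kappa||w||^2 + lambda||w||_1:
  # active coordinates have zero subgradient, inactive ones a bounded one.
  kkt_violation <- function(w, z, r, lambda, kappa) {
    g <- -2 * crossprod(z, r - z %*% w) + 2 * kappa * w
    max(vapply(seq_along(w), function(j) {
      if (w[j] != 0) abs(g[j] + lambda * sign(w[j]))
      else max(0, abs(g[j]) - lambda)
    }, numeric(1)))
  }
  set.seed(63)
  k <- 4; p <- 6
  z <- matrix(rnorm(k * p), k, p)
  r <- rnorm(k)
  for (params in list(c(0.3, 0.01), c(1, 0.5), c(0.05, 0))) {
    lambda <- params[1]; kappa <- params[2]
    cfg <- sparse_config(lasso_lambda = lambda, ridge_kappa = kappa)
    w_pkg <- gcpca:::elastic_net_step(diag(k), matrix(r), cfg, z)
    expect_lt(kkt_violation(w_pkg, z, r, lambda, kappa), 1e-6)
    obj_pkg <- enet_objective(w_pkg, z, r, lambda, kappa)
    # no worse than the zero vector or random perturbations of itself
    expect_lte(obj_pkg, enet_objective(numeric(p), z, r, lambda, kappa) + 1e-10)
    for (i in 1:20) {
      expect_lte(obj_pkg, enet_objective(w_pkg + rnorm(p, sd = 0.01), z, r,
                                         lambda, kappa))
    }
  }
})

test_that("elastic-net step agrees with glmnet at the pure-lasso corner", {
  # kappa = 0 maps exactly onto glmnet's gaussian objective with alpha = 1
  set.seed(68)
  k <- 5; p <- 7
  z <- matrix(rnorm(k * p), k, p)
  r <- rnorm(k)
  lambda <- 0.6
  cfg <- sparse_config(lasso_lambda = lambda, ridge_kappa = 0)
  w_pkg <- gcpca:::elastic_net_step(diag(k), matrix(r), cfg, z)
  fit <- glmnet::glmnet(z, r, alpha = 1, lambda = lambda / (2 * k) * c(16, 4, 1),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14, maxit = 1e7)
  w_glm <- as.numeric(fit$beta[, 3])
  expect_equal(drop(w_pkg), w_glm, tolerance = 1e-5)
})

test_that("procrustes_step returns the best-aligned orthonormal matrix", {
  set.seed(64)
  b <- qr.Q(qr(matrix(rnorm(12), 4, 3)))
  expect_equal(procrustes_step(diag(4), b), b, tolerance = 1e-10)

  g <- matrix(rnorm(9), 3)
  theta_sqrt <- symmetric_sqrt(crossprod(g) + diag(3))
  bb <- matrix(rnorm(6), 3, 2)
  y <- procrustes_step(theta_sqrt, bb)
  expect_equal(crossprod(y), diag(2), tolerance = 1e-10)
  # polar-decomposition oracle on the target
  target <- theta_sqrt %*% theta_sqrt %*% bb
  sv <- svd(target)
  expect_equal(y, sv$u %*% t(sv$v), tolerance = 1e-10)
  # maximizes trace alignment among random orthonormal competitors
  align <- sum(diag(crossprod(y, target)))
  for (i in 1:25) {
    q <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
    expect_lte(sum(diag(crossprod(q, target))), align + 1e-10)
  }
  expect_error(procrustes_step(diag(3), cbind(b[1:3, 1], b[1:3, 1])),
               "rank deficient")
})

test_that("sparse fit limits: lambda = 0 is dense, huge lambda is empty", {
  pr <- random_pair(60, 5, seed = 65, scale_a = seq(2, 1, length.out = 5))
  dense <- fit_gcpca(pr, "v4")
  s0 <- fit_sparse_gcpca(pr, "v4", lasso_lambda = 0, ridge_kappa = 0)
  expect_equal(abs(s0$loadings), abs(dense$loadings), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(s0$eigenvalues, dense$eigenvalues, tolerance = 1e-6)

  shuge <- fit_sparse_gcpca(pr, "v4", lasso_lambda = 1e5)
  expect_true(all(shuge$loadings == 0))
  expect_equal(unname(shuge$sparsity$nonzero), rep(0L, 5))

  smid <- fit_sparse_gcpca(pr, "v4", lasso_lambda = 0.4)
  nz <- sum(smid$loadings != 0)
  expect_gt(nz, 0)
  expect_lt(nz, 25)
})

test_that("sparse fit on the benchmark concentrates support on ground truth", {
  truth <- generate_benchmark_pair(800, seed = 1)
  std <- standardize_pair(truth$pair)
  fit <- fit_sparse_gcpca(std, "v4", lasso_lambda = 1, n_components = 100)
  k <- ncol(fit$loadings)
  top_support <- which(rowSums(fit$loadings[, 1:2] != 0) > 0)
  bottom_support <- which(rowSums(fit$loadings[, (k - 1):k] != 0) > 0)
  expect_true(all(top_support %in% truth$enriched_a))
  expect_true(all(bottom_support %in% truth$enriched_b))
  expect_gt(length(top_support), 0)
  expect_gt(length(bottom_support), 0)
})

test_that("sparsity decreases monotonically in lambda on a path", {
  pr <- random_pair(50, 4, seed = 66, scale_a = c(2, 1.5, 1, 1))
  path <- sparsity_path(pr, "v4", lambda_grid = c(0.01, 0.5, 50),
                        n_components = 2)
  totals <- tapply(path$nonzero, path$lasso_lambda, sum)
  expect_true(all(diff(totals[order(as.numeric(names(totals)))]) <= 0))
})

test_that("rank_features weights loadings by eigenvalue", {
  fake <- gcpca:::new_gcpca_fit(gcpca_variant("v4"),
                                matrix(c(1, 0, 0, 1), 2), c(3, 4),
                                c("f1", "f2"), 2)
  rf <- rank_features(fake)
  expect_equal(rf$score[rf$feature == "f2"], 4)
  expect_equal(rf$score[rf$feature == "f1"], 3)
  expect_equal(rf$feature[1], "f2")

  # single component: scores are |loadings| times the eigenvalue
  pr <- random_pair(40, 4, seed = 67)
  fit <- fit_gcpca(pr, "v4")
  rf1 <- rank_features(fit, components = 1)
  expect_equal(sort(rf1$score, decreasing = TRUE),
               unname(sort(abs(fit$loadings[, 1]) * abs(fit$eigenvalues[1]),
                           decreasing = TRUE)), tolerance = 1e-12)
  # homogeneity: doubling eigenvalues doubles scores
  fit2 <- fit
  fit2$eigenvalues <- 2 * fit2$eigenvalues
  expect_equal(rank_features(fit2)$score, 2 * rank_features(fit)$score)
  expect_error(rank_features(fit, components = integer(0)), "empty")
})
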