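# Independent oracles, deliberately using different numerical routes than
# the package implementation.

# Generalized eigendecomposition of (num, den) via the non-symmetric
# eigenproblem den^-1 num, for small PD denominators.
generalized_eigen_oracle <- function(num, den) {
  e <- eigen(solve(den, num))
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  list(values = vals, vectors = vecs)
}

# Covariance by explicit accumulation of outer products.
covariance_oracle <- function(x) {
  n <- nrow(x)
  acc <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(n)) acc <- acc + tcrossprod(x[i, ])
  acc / (n - 1)
}

# Elastic-net objective of the sparse subproblem in feature-space
# coefficients w: ||r - Z w||^2 + kappa ||w||^2 + lambda ||w||_1.
enet_objective <- function(w, z, r, lambda, kappa) {
  sum((r - z %*% w)^2) + kappa * sum(w^2) + lambda * sum(abs(w))
}

# Plain cyclic coordinate descent for the same objective (soft thresholding),
# independent of glmnet.
enet_cd_oracle <- function(z, r, lambda, kappa, iters = 2000, tol = 1e-12) {
  p <- ncol(z)
  w <- numeric(p)
  zz <- colSums(z^2)
  resid <- r
  for (it in seq_len(iters)) {
    w_old <- w
    for (j in seq_len(p)) {
      rho <- sum(z[, j] * resid) + zz[j] * w[j]
      wj <- sign(rho) * max(abs(rho) - lambda / 2, 0) / (zz[j] + kappa)
      if (wj != w[j]) {
        resid <- resid - z[, j] * (wj - w[j])
        w[j] <- wj
      }
    }
    if (max(abs(w - w_old)) < tol) break
  }
  w
}
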