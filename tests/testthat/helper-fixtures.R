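# Shared fixtures: small random condition pairs built in code.

# Random Gaussian pair, optionally with an anisotropic condition A.
random_pair <- function(n = 40, p = 5, seed = 1, scale_a = NULL) {
  set.seed(seed)
  a <- matrix(rnorm(n * p), n, p)
  if (!is.null(scale_a)) a <- a %*% diag(scale_a)
  b <- matrix(rnorm(n * p), n, p)
  condition_pair(a, b)
}

# Center both conditions (the transforms the fit entry points apply).
preprocess_pair_for_test <- function(pr) {
  condition_pair(center_features(pr$a), center_features(pr$b))
}

# Pair whose centered covariances are exactly diagonal: data columns built
# from disjoint orthogonal designs so that C_A = diag(var_a) and
# C_B = diag(var_b) hold exactly.
diagonal_pair <- function(var_a, var_b, n = 64) {
  p <- length(var_a)
  stopifnot(length(var_b) == p, n %% 2 == 0, n >= 2 * p)
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  mk <- function(v) {
    # orthonormal columns, zero mean; scale to target sample variance
    sweep(base, 2, sqrt(v * (n - 1)), "*")
  }
  condition_pair(mk(var_a), mk(var_b))
}
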