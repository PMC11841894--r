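#' Orthonormal basis of the joint principal subspace
#'
#' Builds the projection matrix `J` whose columns are the principal axes of
#' the row-wise concatenation of the two (preprocessed) condition matrices,
#' keeping only directions with non-negligible singular value. Projecting the
#' contrast problem into this basis removes directions along which the pooled
#' data has essentially zero variance, which would otherwise make the
#' denominator of the contrastive objectives singular.
#'
#' @param pair A [condition_pair()], already preprocessed as desired.
#' @param rank_tol Relative singular-value tolerance: directions with singular
#'   value below `rank_tol * max(singular value)` are excluded. Default 1e-10.
#' @return List with `basis_j` (p x k, orthonormal columns) and `rank_k`.
#' @examples
#' pr <- condition_pair(matrix(rnorm(250), 50), matrix(rnorm(250), 50))
#' build_shared_basis(pr)$rank_k
#' @export
build_shared_basis <- function(pair, rank_tol = 1e-10) {
  stopifnot(inherits(pair, "condition_pair"))
  z <- rbind(pair$a, pair$b)
  sv <- svd(z, nu = 0)
  if (sv$d[1] <= 0) stop("all-zero data: no principal subspace", call. = FALSE)
  k <- sum(sv$d > rank_tol * sv$d[1])
  list(basis_j = sv$v[, seq_len(k), drop = FALSE], rank_k = k)
}

#' Symmetric positive-definite matrix square root
#'
#' Returns the unique symmetric `M` with `M %*% M = s`, via
#' eigendecomposition. Used to whiten the denominator covariance so that the
#' contrast eigenproblem becomes symmetric.
#'
#' @param s Symmetric positive-definite matrix.
#' @return Symmetric matrix `M`; the attribute `"inverse"` holds `solve(M)`
#'   computed from the same eigendecomposition.
#' @examples
#' symmetric_sqrt(diag(c(4, 9)))
#' @export
symmetric_sqrt <- function(s) {
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop("matrix is not positive definite (smallest eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  m <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  m <- (m + t(m)) / 2
  minv <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  attr(m, "inverse") <- (minv + t(minv)) / 2
  m
}

# Restrict the shared basis so that the denominator is positive definite on
# it, then return J, M = sqrt(J' den J) and its inverse. Directions of the
# denominator with eigenvalue <= rank_tol * max are removed from J: the
# pooled-data basis guarantees PD for the v4 denominator (A + B), but B alone
# (v2/v3) can still be singular inside the span of J.
normalized_problem <- function(basis_j, numerator, denominator, rank_tol = 1e-10,
                               variant_name = "gcPCA") {
  j <- basis_j
  den_j <- crossprod(j, denominator %*% j)
  e <- eigen((den_j + t(den_j)) / 2, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values)
  if (max(e$values) <= 0 || !any(keep)) {
    stop("denominator covariance is not positive definite on the shared ",
         "basis (", variant_name, "); largest eigenvalue ",
         format(max(e$values)), call. = FALSE)
  }
  if (!all(keep)) {
    j <- j %*% e$vectors[, keep, drop = FALSE]
    den_j <- crossprod(j, denominator %*% j)
  }
  m <- symmetric_sqrt(den_j)
  minv <- attr(m, "inverse")
  attr(m, "inverse") <- NULL
  reduced <- minv %*% crossprod(j, numerator %*% j) %*% minv
  list(basis_j = j, sqrt_m = m, sqrt_m_inv = minv,
       reduced_matrix = (reduced + t(reduced)) / 2, rank_k = ncol(j))
}

# Sign convention: make the largest-magnitude entry of each column positive.
fix_signs <- function(loadings, companion = NULL) {
  flip <- vapply(seq_len(ncol(loadings)), function(i) {
    col <- loadings[, i]
    col[which.max(abs(col))] < 0
  }, logical(1))
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  if (!is.null(companion)) {
    companion[, flip] <- -companion[, flip, drop = FALSE]
    return(list(loadings = loadings, companion = companion))
  }
  loadings
}

unit_columns <- function(x) {
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- 1
  sweep(x, 2, nrm, "/")
}

new_gcpca_fit <- function(variant, loadings, eigenvalues, feature_names,
                          rank_k, components_y = NULL, extra = list()) {
  colnames(loadings) <- paste0("gcPC", seq_len(ncol(loadings)))
  rownames(loadings) <- feature_names
  structure(
    c(list(variant = variant, loadings = loadings, eigenvalues = eigenvalues,
           components_y = components_y, feature_names = feature_names,
           rank_k = rank_k),
      extra),
    class = "gcpca_fit"
  )
}

#' Fit generalized contrastive PCA
#'
#' Finds the directions along which variance differs most between condition A
#' and condition B, under the objective selected by `variant` (see
#' [gcpca_variant()]). The contrast problem is projected onto the joint
#' principal subspace `J` of both conditions, the denominator covariance is
#' whitened by its symmetric square root `M`, the resulting symmetric matrix
#' `M^-1 J' N J M^-1` is eigendecomposed, and components are mapped back to
#' feature space as `X = J M^-1 Y`. Loadings columns are rescaled to unit
#' Euclidean norm (the Rayleigh quotients are scale invariant) and signed so
#' the largest-magnitude entry is positive.
#'
#' For the orthogonal variants (`v2.1`, `v3.1`, `v4.1`) components are
#' extracted one at a time, deflating the working basis after each so that
#' loadings are orthonormal in the original feature space; see
#' [fit_orthogonal_gcpca()] for details.
#'
#' @param pair A [condition_pair()], or a matrix/data frame for condition A
#'   (then `b` must be supplied).
#' @param variant A [gcpca_variant()] or its name. Default `"v4"`.
#' @param b Condition B data when `pair` is not a `condition_pair`.
#' @param alpha Alpha hyperparameter, only for `variant = "v1"`.
#' @param n_components Number of components to return; default the full
#'   shared rank `k`.
#' @param center,zscore,l2norm Preprocessing applied to each condition before
#'   fitting (centering on by default; z-scoring implies centering).
#' @param rank_tol Relative tolerance for excluding numerically-zero
#'   directions from the shared basis and the denominator.
#' @return An object of class `gcpca_fit` with elements `loadings`
#'   (p x k, unit-norm columns), `eigenvalues` (descending), `variant`,
#'   `rank_k`, and the fitted `feature_names`. Supports [tidy()], [glance()],
#'   [predict()][predict.gcpca_fit], [autoplot()] and [gcpca_transform()].
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(600), 100, 6) %*% diag(c(3, 1, 1, 1, 1, 1))
#' b <- matrix(rnorm(600), 100, 6)
#' fit <- fit_gcpca(condition_pair(a, b), "v4")
#' round(fit$eigenvalues, 2)
#' @seealso [fit_cpca()], [fit_sparse_gcpca()], [gcpca_transform()]
#' @export
fit_gcpca <- function(pair, variant = "v4", b = NULL, alpha = NULL,
                      n_components = NULL, center = TRUE, zscore = FALSE,
                      l2norm = FALSE, rank_tol = 1e-10) {
  if (!inherits(pair, "condition_pair")) {
    if (is.null(b)) stop("supply a condition_pair, or both `pair` (A) and `b`",
                         call. = FALSE)
    pair <- condition_pair(pair, b)
  }
  variant <- as_gcpca_variant(variant, alpha = alpha)
  pair <- preprocess_pair(pair, center = center, zscore = zscore, l2norm = l2norm)

  if (variant$base == "v1" && !variant$orthogonal) {
    return(fit_cpca_impl(pair, variant, n_components))
  }
  if (variant$orthogonal) {
    return(fit_orthogonal_gcpca(pair, variant, n_components = n_components,
                                rank_tol = rank_tol, .preprocessed = TRUE))
  }

  cov_a <- compute_covariance(pair$a)
  cov_b <- compute_covariance(pair$b)
  mats <- variant_matrices(variant, cov_a, cov_b)
  sb <- build_shared_basis(pair, rank_tol = rank_tol)
  np <- normalized_problem(sb$basis_j, mats$numerator, mats$denominator,
                           rank_tol = rank_tol, variant_name = variant$name)
  e <- eigen(np$reduced_matrix, symmetric = TRUE)
  y <- e$vectors
  loadings <- np$basis_j %*% (np$sqrt_m_inv %*% y)
  loadings <- unit_columns(loadings)
  fs <- fix_signs(loadings, y)
  keep <- seq_len(min(n_components %||% np$rank_k, np$rank_k))
  new_gcpca_fit(variant, fs$loadings[, keep, drop = FALSE], e$values[keep],
                pair$feature_names, np$rank_k,
                components_y = fs$companion[, keep, drop = FALSE])
}

fit_cpca_impl <- function(pair, variant, n_components = NULL) {
  cov_a <- compute_covariance(pair$a)
  cov_b <- compute_covariance(pair$b)
  contrast <- cov_a - variant$alpha * cov_b
  e <- eigen((contrast + t(contrast)) / 2, symmetric = TRUE)
  keep <- seq_len(min(n_components %||% ncol(cov_a), ncol(cov_a)))
  loadings <- fix_signs(e$vectors[, keep, drop = FALSE])
  new_gcpca_fit(variant, loadings, e$values[keep], pair$feature_names,
                ncol(cov_a))
}

#' Fit classic contrastive PCA
#'
#' Eigendecomposition of `C_A - alpha * C_B` in feature space. With
#' `alpha = 0` this is ordinary PCA of condition A. Equivalent to
#' `fit_gcpca(pair, "v1", alpha = alpha)`.
#'
#' @inheritParams fit_gcpca
#' @param alpha Nonnegative weight on the background covariance `C_B`.
#' @return A `gcpca_fit`; loadings are orthonormal in feature space.
#' @examples
#' pr <- condition_pair(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
#' fit_cpca(pr, alpha = 1)$eigenvalues
#' @export
fit_cpca <- function(pair, alpha, b = NULL, n_components = NULL, center = TRUE,
                     zscore = FALSE, l2norm = FALSE) {
  fit_gcpca(pair, variant = "v1", b = b, alpha = alpha,
            n_components = n_components, center = center, zscore = zscore,
            l2norm = l2norm)
}

#' Project data onto fitted contrastive components
#'
#' @param model A `gcpca_fit`.
#' @param data Matrix or data frame with the same features the model was
#'   fitted on.
#' @return A tibble of scores, one column per component (`gcPC1`, ...).
#' @examples
#' pr <- condition_pair(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
#' fit <- fit_gcpca(pr, "v4")
#' gcpca_transform(fit, pr$a)[1:3, 1:2]
#' @export
gcpca_transform <- function(model, data) {
  stopifnot(inherits(model, "gcpca_fit"))
  data <- as_numeric_matrix(data, "data")
  if (ncol(data) != nrow(model$loadings)) {
    stop("data has ", ncol(data), " features but the model was fitted on ",
         nrow(model$loadings), call. = FALSE)
  }
  scores <- data %*% model$loadings
  tibble::as_tibble(scores)
}

#' @export
#' @rdname gcpca_transform
#' @param object,newdata,... `predict()` method aliases for `model`, `data`.
predict.gcpca_fit <- function(object, newdata, ...) {
  gcpca_transform(object, newdata)
}

#' @export
print.gcpca_fit <- function(x, ...) {
  cat("<gcpca_fit> variant ", x$variant$name,
      if (!is.null(x$variant$alpha)) paste0(" (alpha = ", x$variant$alpha, ")"),
      "\n", sep = "")
  cat("  ", nrow(x$loadings), " features, ", ncol(x$loadings),
      " components (shared rank ", x$rank_k, ")\n", sep = "")
  ev <- x$eigenvalues
  show <- utils::head(ev, 5)
  cat("  eigenvalues: ", paste(formatC(show, digits = 3, format = "g"),
                               collapse = ", "),
      if (length(ev) > 5) ", ...", "\n", sep = "")
  if (!is.null(x$sparsity)) {
    cat("  sparse fit: lambda = ", x$sparsity$lasso_lambda, ", ",
        sum(x$sparsity$nonzero), " nonzero loadings\n", sep = "")
  }
  invisible(x)
}
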