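#' Remove a component's span from a working basis
#'
#' Given a column-orthonormal basis and an accepted unit-norm component `x`
#' lying (numerically) in its span, regress `x` out of the basis
#' (`J - x x' J`) and re-orthonormalize with an SVD, keeping one fewer
#' column. The returned basis spans the orthogonal complement of `x` inside
#' `span(J)`.
#'
#' @param basis_j Matrix with orthonormal columns (p x m).
#' @param x Unit-norm vector of length p with a nonzero component in
#'   `span(basis_j)`.
#' @return A p x (m - 1) matrix with orthonormal columns, all orthogonal
#'   to `x`.
#' @examples
#' deflate_basis(diag(3), c(1, 0, 0))
#' @export
deflate_basis <- function(basis_j, x) {
  x <- as.numeric(x)
  if (abs(sum(x^2) - 1) > 1e-8) stop("`x` must have unit norm", call. = FALSE)
  proj <- crossprod(basis_j, x)
  if (sqrt(sum(proj^2)) < 1e-10) {
    stop("`x` is orthogonal to the span of the basis; nothing to deflate",
         call. = FALSE)
  }
  jhat <- basis_j - x %*% crossprod(x, basis_j)
  sv <- svd(jhat, nv = 0)
  sv$u[, seq_len(ncol(basis_j) - 1), drop = FALSE]
}

#' Contrastive components orthogonal in feature space
#'
#' The unconstrained contrastive components are orthogonal only in the
#' whitened space (after multiplication by `M^-1`), not in the original
#' feature space. The `.1` variants restore feature-space orthogonality by
#' extracting one component at a time: solve the reduced eigenproblem on the
#' current basis, accept the extreme eigenvector, map it to feature space,
#' then deflate the basis with [deflate_basis()] and re-whiten before the
#' next iteration. For the symmetric variant (`v4.1`) extraction alternates
#' between the largest (A-enriched) and smallest (B-enriched) eigenvalue; for
#' the asymmetric variants (`v2.1`, `v3.1`) the largest eigenvalue is always
#' taken, since the smallest has no B-enrichment interpretation there.
#' Accepted components are finally re-sorted by descending eigenvalue so the
#' column order matches the unconstrained convention.
#'
#' Usually called through `fit_gcpca(pair, "v4.1")` rather than directly.
#'
#' @inheritParams fit_gcpca
#' @param variant An orthogonal-constraint variant (`v2.1`, `v3.1`, `v4.1`),
#'   or a base variant name which is promoted to its `.1` form.
#' @param .preprocessed Internal: skip preprocessing (already applied).
#' @return A `gcpca_fit` whose loadings are orthonormal in feature space.
#' @examples
#' pr <- condition_pair(matrix(rnorm(400), 80), matrix(rnorm(400), 80))
#' fit <- fit_orthogonal_gcpca(pr, "v4.1", n_components = 3)
#' round(crossprod(fit$loadings), 8)
#' @export
fit_orthogonal_gcpca <- function(pair, variant = "v4.1", n_components = NULL,
                                 center = TRUE, zscore = FALSE, l2norm = FALSE,
                                 rank_tol = 1e-10, .preprocessed = FALSE) {
  stopifnot(inherits(pair, "condition_pair"))
  variant <- as_gcpca_variant(variant)
  if (!variant$orthogonal) variant <- gcpca_variant(paste0(variant$base, ".1"))
  if (variant$base == "v1") {
    stop("cPCA loadings (v1) are already orthogonal in feature space; ",
         "use fit_cpca()", call. = FALSE)
  }
  if (!.preprocessed) {
    pair <- preprocess_pair(pair, center = center, zscore = zscore,
                            l2norm = l2norm)
  }

  cov_a <- compute_covariance(pair$a)
  cov_b <- compute_covariance(pair$b)
  mats <- variant_matrices(variant, cov_a, cov_b)
  sb <- build_shared_basis(pair, rank_tol = rank_tol)
  k_total <- sb$rank_k
  n_components <- min(n_components %||% k_total, k_total)

  basis <- sb$basis_j
  loadings <- matrix(0, ncol(pair$a), n_components)
  eigenvalues <- numeric(n_components)
  take_largest <- TRUE
  for (i in seq_len(n_components)) {
    np <- normalized_problem(basis, mats$numerator, mats$denominator,
                             rank_tol = rank_tol, variant_name = variant$name)
    e <- eigen(np$reduced_matrix, symmetric = TRUE)
    idx <- if (take_largest) 1L else np$rank_k
    x <- np$basis_j %*% (np$sqrt_m_inv %*% e$vectors[, idx])
    x <- x / sqrt(sum(x^2))
    loadings[, i] <- x
    eigenvalues[i] <- e$values[idx]
    if (i < n_components) basis <- deflate_basis(basis, x)
    if (variant$symmetric) take_largest <- !take_largest
  }
  ord <- order(eigenvalues, decreasing = TRUE)
  loadings <- fix_signs(loadings[, ord, drop = FALSE])
  new_gcpca_fit(variant, loadings, eigenvalues[ord], pair$feature_names,
                k_total, extra = list(n_deflations = n_components - 1L))
}
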