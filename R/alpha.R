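#' Candidate alpha values for contrastive PCA
#'
#' Classic contrastive PCA needs the hyperparameter `alpha`; its companion
#' selection procedure surveys a log-spaced grid of alphas, summarises each
#' by the subspace of its top components, clusters the alphas by subspace
#' similarity, and proposes the medoid of each cluster as a representative
#' candidate. Affinity between two alphas is the product of the cosines of
#' the principal angles between their top-`top_k` eigenvector subspaces
#' (1 for identical subspaces, 0 for orthogonal ones). Clustering is spectral
#' clustering on the affinity matrix.
#'
#' @inheritParams fit_gcpca
#' @param n_alphas Number of grid points. Default 40.
#' @param alpha_min,alpha_max Grid range (log-spaced). Defaults 0.01 and 1000.
#' @param top_k Subspace dimension compared between alphas. Default 2.
#' @param n_clusters Number of candidate alphas requested.
#' @return A tibble with columns `alpha` (cluster medoids, ascending) and
#'   `cluster`. Fewer rows than `n_clusters` are returned, with a warning,
#'   when the grid does not support that many distinct subspace clusters.
#' @examples
#' pr <- condition_pair(matrix(rnorm(400), 100), matrix(rnorm(400), 100))
#' select_alphas(pr, n_alphas = 12, n_clusters = 2)
#' @export
select_alphas <- function(pair, n_alphas = 40, alpha_min = 0.01,
                          alpha_max = 1000, top_k = 2, n_clusters = 4,
                          center = TRUE, zscore = FALSE, l2norm = FALSE) {
  stopifnot(inherits(pair, "condition_pair"), n_clusters >= 1, top_k >= 1)
  pair <- preprocess_pair(pair, center = center, zscore = zscore,
                          l2norm = l2norm)
  alphas <- 10^seq(log10(alpha_min), log10(alpha_max), length.out = n_alphas)
  cov_a <- compute_covariance(pair$a)
  cov_b <- compute_covariance(pair$b)
  bases <- lapply(alphas, function(al) {
    ctr <- cov_a - al * cov_b
    eigen((ctr + t(ctr)) / 2, symmetric = TRUE)$vectors[, seq_len(top_k),
                                                        drop = FALSE]
  })
  aff <- subspace_affinity_matrix(bases)
  cl <- cluster_affinity(aff, n_clusters)
  medoids <- vapply(sort(unique(cl)), function(g) {
    members <- which(cl == g)
    within <- aff[members, members, drop = FALSE]
    members[which.max(rowSums(within))]
  }, integer(1))
  out <- tibble::tibble(alpha = alphas[medoids],
                        cluster = seq_along(medoids))
  dplyr::arrange(out, .data$alpha)
}

#' Affinity between two subspaces
#'
#' Product of the cosines of the principal angles between the column spans
#' of two orthonormal-column matrices, i.e. the product of the singular
#' values of `t(q1) %*% q2`.
#'
#' @param q1,q2 Matrices with orthonormal columns and equal row count.
#' @return A number in `[0, 1]`.
#' @examples
#' subspace_affinity(diag(3)[, 1:2], diag(3)[, 1:2])
#' subspace_affinity(diag(4)[, 1:2], diag(4)[, 3:4])
#' @export
subspace_affinity <- function(q1, q2) {
  s <- svd(crossprod(q1, q2), nu = 0, nv = 0)$d
  prod(pmin(pmax(s, 0), 1))
}

subspace_affinity_matrix <- function(bases) {
  n <- length(bases)
  aff <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aff[i, j] <- aff[j, i] <- subspace_affinity(bases[[i]], bases[[j]])
    }
  }
  aff
}

# Spectral clustering on a precomputed affinity matrix, falling back to
# average-linkage hierarchical clustering when the spectral step degenerates
# (e.g. all subspaces essentially identical).
cluster_affinity <- function(aff, n_clusters) {
  n <- nrow(aff)
  if (n_clusters >= n) return(seq_len(n))
  distinct <- sum(!duplicated(round(aff, 8)))
  if (distinct < n_clusters) {
    warning("fewer distinct subspaces than requested clusters; returning ",
            distinct, " candidates", call. = FALSE)
    n_clusters <- max(distinct, 1)
  }
  cl <- tryCatch(
    as.integer(kernlab::specc(kernlab::as.kernelMatrix(aff),
                              centers = n_clusters)),
    error = function(e) {
      warning("spectral clustering degenerated (",
              conditionMessage(e),
              "); falling back to hierarchical clustering", call. = FALSE)
      stats::cutree(stats::hclust(stats::as.dist(1 - aff), method = "average"),
                    k = n_clusters)
    })
  cl
}
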