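#' Sparse-fit configuration
#'
#' Parameters of the alternating elastic-net / Procrustes algorithm used by
#' [fit_sparse_gcpca()].
#'
#' @param lasso_lambda Nonnegative lasso weight applied to the feature-space
#'   image of each coefficient vector; the same value is shared across all
#'   components. There is no universal default — use
#'   [sparsity_path()] to survey nonzero counts over a lambda grid.
#' @param ridge_kappa Nonnegative ridge weight, a small value whose role is
#'   repairing rank deficiency. Default `1e-4`.
#' @param n_components Number of components to sparsify; default the full
#'   shared rank (so both A-enriched and B-enriched ends are available for
#'   symmetric variants).
#' @param max_iterations Maximum outer (alternating) iterations. Default 200.
#' @param convergence_tol Relative change in the coefficient matrix below
#'   which the alternation stops. Default 1e-6.
#' @param tikhonov_epsilon Shift added beyond `|min eigenvalue|` when
#'   repairing an indefinite target matrix; default `1e-6 * trace(theta)/k`,
#'   resolved at fit time (`NULL` here).
#' @return A list of class `sparse_config`.
#' @export
sparse_config <- function(lasso_lambda, ridge_kappa = 1e-4, n_components = NULL,
                          max_iterations = 200, convergence_tol = 1e-6,
                          tikhonov_epsilon = NULL) {
  stopifnot(is.numeric(lasso_lambda), length(lasso_lambda) == 1,
            lasso_lambda >= 0, ridge_kappa >= 0, max_iterations >= 1,
            convergence_tol > 0)
  if (!is.null(tikhonov_epsilon) && tikhonov_epsilon <= 0) {
    stop("`tikhonov_epsilon` must be positive", call. = FALSE)
  }
  structure(list(lasso_lambda = lasso_lambda, ridge_kappa = ridge_kappa,
                 n_components = n_components, max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 tikhonov_epsilon = tikhonov_epsilon),
            class = "sparse_config")
}

#' Variant target matrix for the sparse algorithm
#'
#' The sparse algorithm replaces the covariance of the sparse-PCA regression
#' view with a variant-specific target: the whitened contrast matrix
#' `theta = M^-1 J' N J M^-1` for v2-v4 (with `M` the square root of the
#' variant's denominator restricted to `J`), or `C_A - alpha C_B` in raw
#' feature space for v1.
#'
#' @param variant A [gcpca_variant()] (base form; sparsity cannot be combined
#'   with the orthogonality constraint).
#' @param problem A normalized problem as produced internally by the dense
#'   fit: list with `basis_j`, `sqrt_m_inv` and `reduced_matrix` (ignored for
#'   v1, where `cov_a`/`cov_b` are used directly).
#' @param cov_a,cov_b Feature-space covariances (required for v1).
#' @return Symmetric target matrix `theta`.
#' @export
build_theta <- function(variant, problem = NULL, cov_a = NULL, cov_b = NULL) {
  variant <- as_gcpca_variant(variant, alpha = variant$alpha)
  if (variant$orthogonal) {
    stop("sparse solutions cannot be combined with the orthogonality ",
         "constraint", call. = FALSE)
  }
  if (variant$base == "v1") {
    if (is.null(cov_a) || is.null(cov_b)) {
      stop("v1 target needs `cov_a` and `cov_b`", call. = FALSE)
    }
    th <- cov_a - variant$alpha * cov_b
    return((th + t(th)) / 2)
  }
  if (is.null(problem)) stop("variant/problem mismatch: `problem` required",
                             call. = FALSE)
  problem$reduced_matrix
}

#' Shift an indefinite symmetric matrix to positive definiteness
#'
#' Adds `(|min eigenvalue| + epsilon) * I` when the smallest eigenvalue is
#' nonpositive, leaving the eigenvectors (and eigenvalue ordering) unchanged.
#' The v3/v4 targets are bounded below by -1, so a modest shift always
#' suffices; the same repair is applied to the possibly unbounded v1 target.
#'
#' @param theta Symmetric matrix.
#' @param epsilon Positive shift margin; default `1e-6 * mean(diag)` scale,
#'   i.e. `1e-6 * trace(theta)/k` floored at `1e-12`.
#' @return Positive-definite matrix.
#' @examples
#' tikhonov_repair(diag(c(0.5, -0.5)), epsilon = 0.01)
#' @export
tikhonov_repair <- function(theta, epsilon = NULL) {
  theta <- (theta + t(theta)) / 2
  if (is.null(epsilon)) {
    epsilon <- max(1e-6 * sum(diag(theta)) / ncol(theta), 1e-12)
  }
  lam_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min > 0) return(theta)
  theta + (abs(lam_min) + epsilon) * diag(ncol(theta))
}

# Elastic-net subproblem: minimize, over feature-space coefficients w,
#   || theta_sqrt %*% y - Z w ||^2 + kappa ||w||^2 + lambda ||w||_1,
# where Z = theta_sqrt %*% M %*% t(J) maps feature space into the whitened
# target space (Z = theta_sqrt for v1). The penalties act on the
# feature-space image J M^-1 beta = w directly, as the objective requires.
# Solved exactly by cyclic coordinate descent with soft thresholding,
# warm-started across outer iterations; the lambda = 0 ridge/least-squares
# limits use closed forms. (Solutions satisfy the subgradient optimality
# conditions of the penalized objective as written, with the lasso and ridge
# weights applied verbatim.)

#' @keywords internal
elastic_net_step <- function(theta_sqrt, rotation_y, config, design,
                             warm = NULL) {
  p <- ncol(design)
  responses <- theta_sqrt %*% rotation_y
  lam <- config$lasso_lambda
  kap <- config$ridge_kappa

  if (lam == 0) {
    if (kap == 0) {
      # min-norm least squares via the pseudoinverse
      sv <- svd(design)
      pos <- sv$d > 1e-12 * max(sv$d)
      w <- sv$v[, pos, drop = FALSE] %*%
        ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], responses))
    } else {
      w <- solve(crossprod(design) + kap * diag(p),
                 crossprod(design, responses))
    }
    return(w)
  }

  zz <- colSums(design^2)
  active <- zz > 0
  w <- warm %||% matrix(0, p, ncol(rotation_y))
  for (j in seq_len(ncol(rotation_y))) {
    wj <- w[, j]
    resid <- responses[, j] - design %*% wj
    for (sweep_i in seq_len(1000L)) {
      max_delta <- 0
      for (c in which(active)) {
        rho <- sum(design[, c] * resid) + zz[c] * wj[c]
        new_c <- sign(rho) * max(abs(rho) - lam / 2, 0) / (zz[c] + kap)
        d <- new_c - wj[c]
        if (d != 0) {
          resid <- resid - design[, c] * d
          wj[c] <- new_c
          max_delta <- max(max_delta, abs(d))
        }
      }
      if (max_delta < 1e-8) break
    }
    w[, j] <- wj
  }
  w
}

#' Procrustes rotation toward a target matrix
#'
#' The orthonormal-column matrix best aligned (in trace inner product) with
#' `theta %*% b`, obtained as the polar factor `U V'` of its SVD. In the
#' alternating sparse algorithm this updates the rotation `Y` for fixed
#' coefficients `B`.
#'
#' @param theta_sqrt Square root of the (repaired) target matrix; the target
#'   used is `theta_sqrt %*% theta_sqrt`.
#' @param coefficient_matrix_b Coefficients in the whitened space, full
#'   column rank.
#' @return Matrix with orthonormal columns, same shape as
#'   `coefficient_matrix_b`.
#' @export
procrustes_step <- function(theta_sqrt, coefficient_matrix_b) {
  target <- theta_sqrt %*% (theta_sqrt %*% coefficient_matrix_b)
  if (qr(coefficient_matrix_b)$rank < ncol(coefficient_matrix_b)) {
    stop("coefficient matrix is rank deficient; reduce n_components or ",
         "lasso_lambda", call. = FALSE)
  }
  sv <- svd(target)
  sv$u %*% t(sv$v)
}

procrustes_rotation <- function(theta_rep, b) {
  sv <- svd(theta_rep %*% b)
  sv$u %*% t(sv$v)
}

# One branch of the alternating algorithm: elastic-net coefficient updates
# against the (repaired) target, Procrustes rotation updates, until the
# feature-space coefficients stabilise.
sparse_alternate <- function(theta, y, config, design_map, p) {
  theta_rep <- tikhonov_repair(theta, epsilon = config$tikhonov_epsilon)
  theta_sqrt <- symmetric_sqrt(theta_rep)
  attr(theta_sqrt, "inverse") <- NULL
  design <- theta_sqrt %*% design_map  # k x p
  w <- matrix(0, p, ncol(y))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    w_new <- elastic_net_step(theta_sqrt, y, config, design, warm = w)
    nz <- colSums(w_new != 0) > 0
    if (any(nz)) {
      b_k <- design_map %*% w_new  # coefficients in whitened space
      y[, nz] <- procrustes_rotation(theta_rep, b_k[, nz, drop = FALSE])
    }
    delta <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), 1e-12)
    w <- w_new
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }
  list(w = w, converged = converged, iterations = iterations)
}

#' Fit sparse generalized contrastive PCA
#'
#' Sparsifies the contrastive components with an elastic net, recasting the
#' problem as a penalized regression on the whitened target matrix `theta`
#' (see [build_theta()]). Starting from the dense components, the algorithm
#' alternates (i) an elastic-net update of the coefficient matrix for a fixed
#' rotation and (ii) a Procrustes-rotation update for fixed coefficients,
#' until the coefficients stabilise. The lasso and ridge penalties are
#' applied to the feature-space image of each coefficient vector, so the
#' final loadings `J M^-1 B` are sparse in the original features. Indefinite
#' targets (possible for v1/v3/v4) are first made positive definite with
#' [tikhonov_repair()], which leaves the components unchanged.
#'
#' @inheritParams fit_gcpca
#' @param config A [sparse_config()]; alternatively pass `lasso_lambda` (and
#'   friends) directly.
#' @param lasso_lambda,ridge_kappa Shortcut parameters used when `config` is
#'   missing.
#' @return A `gcpca_fit` with sparse unit-norm loadings (all-zero columns are
#'   left at zero and flagged), eigenvalues equal to the variant's Rayleigh
#'   quotient evaluated at each loading (`NA` for fully-sparsified columns),
#'   and a `sparsity` element recording per-component nonzero counts,
#'   penalties and iterations used.
#' @examples
#' set.seed(2)
#' pr <- condition_pair(matrix(rnorm(900), 150, 6), matrix(rnorm(900), 150, 6))
#' fit <- fit_sparse_gcpca(pr, "v4", lasso_lambda = 0.2, n_components = 2)
#' fit$sparsity$nonzero
#' @export
fit_sparse_gcpca <- function(pair, variant = "v4", config = NULL,
                             lasso_lambda = NULL, ridge_kappa = 1e-4,
                             b = NULL, alpha = NULL, n_components = NULL,
                             center = TRUE, zscore = FALSE, l2norm = FALSE,
                             rank_tol = 1e-10) {
  if (!inherits(pair, "condition_pair")) {
    if (is.null(b)) stop("supply a condition_pair, or both `pair` (A) and `b`",
                         call. = FALSE)
    pair <- condition_pair(pair, b)
  }
  variant <- as_gcpca_variant(variant, alpha = alpha)
  if (variant$orthogonal) {
    stop("sparse solutions cannot be combined with the orthogonality ",
         "constraint", call. = FALSE)
  }
  if (is.null(config)) {
    if (is.null(lasso_lambda)) {
      stop("supply `config` (sparse_config()) or `lasso_lambda`", call. = FALSE)
    }
    config <- sparse_config(lasso_lambda, ridge_kappa = ridge_kappa,
                            n_components = n_components)
  } else if (!is.null(n_components)) {
    config$n_components <- n_components
  }
  pair <- preprocess_pair(pair, center = center, zscore = zscore,
                          l2norm = l2norm)

  cov_a <- compute_covariance(pair$a)
  cov_b <- compute_covariance(pair$b)
  p <- ncol(pair$a)

  if (variant$base == "v1") {
    theta <- build_theta(variant, cov_a = cov_a, cov_b = cov_b)
    j <- diag(p); m_inv <- diag(p); map_back <- diag(p)
    design_map <- diag(p)  # beta is already in feature space
    rank_k <- p
  } else {
    mats <- variant_matrices(variant, cov_a, cov_b)
    sb <- build_shared_basis(pair, rank_tol = rank_tol)
    np <- normalized_problem(sb$basis_j, mats$numerator, mats$denominator,
                             rank_tol = rank_tol, variant_name = variant$name)
    theta <- build_theta(variant, problem = np)
    j <- np$basis_j
    m_inv <- np$sqrt_m_inv
    map_back <- j %*% m_inv           # beta (whitened) -> feature space
    design_map <- np$sqrt_m %*% t(j)  # feature space w -> beta
    rank_k <- np$rank_k
  }

  k <- nrow(theta)
  ncomp <- min(config$n_components %||% k, k)
  dense_e <- eigen((theta + t(theta)) / 2, symmetric = TRUE)
  eig_dense <- dense_e$values[seq_len(ncomp)]

  # For the symmetric objective, the most negative components are the leading
  # components of the A/B-swapped problem; sparsifying them against the
  # Tikhonov-shifted theta would leave them with ~zero regression signal, so
  # they are run against -theta instead. For asymmetric objectives only the
  # top end has an enrichment meaning and a single branch is used.
  if (variant$symmetric) {
    pos <- which(eig_dense >= 0)
    neg <- setdiff(seq_len(ncomp), pos)
  } else {
    pos <- seq_len(ncomp)
    neg <- integer(0)
  }

  w <- matrix(0, p, ncomp)
  iterations <- 0L
  converged <- TRUE
  run_branch <- function(theta_branch, idx) {
    y0 <- eigen((theta_branch + t(theta_branch)) / 2,
                symmetric = TRUE)$vectors[, idx, drop = FALSE]
    sparse_alternate(theta_branch, y0, config, design_map, p)
  }
  if (length(pos)) {
    br <- run_branch(theta, seq_along(pos))
    w[, pos] <- br$w
    iterations <- max(iterations, br$iterations)
    converged <- converged && br$converged
  }
  if (length(neg)) {
    # leading components of -theta = most negative of theta, in reverse order
    br <- run_branch(-theta, seq_along(neg))
    w[, rev(neg)] <- br$w
    iterations <- max(iterations, br$iterations)
    converged <- converged && br$converged
  }
  if (!converged && config$lasso_lambda > 0) {
    warning("sparse alternation did not converge in ", config$max_iterations,
            " iterations", call. = FALSE)
  }

  nonzero <- colSums(w != 0)
  loadings <- unit_columns(w)
  loadings <- fix_signs(loadings)
  mats_all <- variant_matrices(variant, cov_a, cov_b)
  eigenvalues <- vapply(seq_len(ncomp), function(i) {
    x <- loadings[, i]
    if (all(x == 0)) return(NA_real_)
    num <- drop(crossprod(x, mats_all$numerator %*% x))
    if (variant$base == "v1") num else {
      num / drop(crossprod(x, mats_all$denominator %*% x))
    }
  }, numeric(1))

  fit <- new_gcpca_fit(variant, loadings, eigenvalues, pair$feature_names,
                       rank_k,
                       extra = list(sparsity = list(
                         lasso_lambda = config$lasso_lambda,
                         ridge_kappa = config$ridge_kappa,
                         nonzero = nonzero, iterations = iterations,
                         converged = converged,
                         dense_eigenvalues = eig_dense)))
  fit
}

#' Survey sparsity over a lasso-penalty grid
#'
#' Fits [fit_sparse_gcpca()] over a log-spaced grid of `lasso_lambda` values
#' and reports the nonzero-loading count per component, to guide the choice
#' of penalty (which has no universal default).
#'
#' @inheritParams fit_sparse_gcpca
#' @param lambda_grid Penalty values; default 10 log-spaced values in
#'   `[1e-3, 10]`.
#' @return A tibble with columns `lasso_lambda`, `component`, `nonzero`.
#' @export
sparsity_path <- function(pair, variant = "v4", lambda_grid = NULL,
                          n_components = 2, ...) {
  lambda_grid <- lambda_grid %||% 10^seq(-3, 1, length.out = 10)
  res <- lapply(lambda_grid, function(lam) {
    fit <- fit_sparse_gcpca(pair, variant, lasso_lambda = lam,
                            n_components = n_components, ...)
    tibble::tibble(lasso_lambda = lam,
                   component = seq_along(fit$sparsity$nonzero),
                   nonzero = fit$sparsity$nonzero)
  })
  dplyr::bind_rows(res)
}

#' Rank features by loading magnitude weighted by eigenvalue
#'
#' Scores each feature as the l2-norm, over the selected components, of its
#' loading multiplied by the component eigenvalue:
#' `score_f = sqrt(sum_c (loading_fc * eigenvalue_c)^2)`. This is the
#' gene-prioritisation score used for expression data: features driving
#' strongly contrastive components rank first.
#'
#' @param model A fitted `gcpca_fit`.
#' @param components Integer vector of component indices; default all
#'   components with non-`NA` eigenvalues.
#' @return A tibble with columns `feature`, `score`, `rank`, sorted by
#'   descending score.
#' @examples
#' pr <- condition_pair(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
#' rank_features(fit_gcpca(pr, "v4"), components = 1:2)
#' @export
rank_features <- function(model, components = NULL) {
  stopifnot(inherits(model, "gcpca_fit"))
  components <- components %||% which(!is.na(model$eigenvalues))
  if (length(components) == 0) stop("empty component subset", call. = FALSE)
  if (any(components < 1 | components > ncol(model$loadings))) {
    stop("component indices out of range", call. = FALSE)
  }
  l <- model$loadings[, components, drop = FALSE]
  ev <- model$eigenvalues[components]
  weighted <- sweep(l, 2, ev, "*")
  score <- unname(sqrt(rowSums(weighted^2)))
  out <- tibble::tibble(feature = model$feature_names, score = score)
  out <- dplyr::arrange(out, dplyr::desc(score))
  out$rank <- seq_len(nrow(out))
  out
}
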