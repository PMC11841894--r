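#' Feature-wise preprocessing transforms
#'
#' Deterministic column-wise transforms used before a contrastive fit:
#' `center_features()` removes each column mean, `zscore_features()`
#' standardises each column to mean 0 / sample standard deviation 1, and
#' `l2_normalize_features()` rescales each column to unit Euclidean norm.
#' All three operate on the samples-by-features orientation and accept a
#' matrix or an all-numeric data frame.
#'
#' @param data Numeric matrix or data frame, samples in rows, features in
#'   columns.
#' @return A numeric matrix of the same shape.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 8), ncol = 2)
#' colMeans(center_features(m))
#' apply(zscore_features(m), 2, sd)
#' @name preprocessing
NULL

#' @rdname preprocessing
#' @export
center_features <- function(data) {
  data <- as_numeric_matrix(data, "data")
  sweep(data, 2, colMeans(data), "-")
}

#' @rdname preprocessing
#' @export
zscore_features <- function(data) {
  data <- as_numeric_matrix(data, "data")
  if (nrow(data) < 2) stop("z-scoring needs at least 2 samples", call. = FALSE)
  ctr <- center_features(data)
  s <- sqrt(colSums(ctr^2) / (nrow(data) - 1))
  zero <- s == 0
  if (any(zero)) {
    nm <- colnames(data) %||% as.character(seq_len(ncol(data)))
    stop("zero-variance feature(s) cannot be z-scored: ",
         paste(nm[zero], collapse = ", "),
         " (drop them first, e.g. with drop_near_zero_variance())",
         call. = FALSE)
  }
  sweep(ctr, 2, s, "/")
}

#' @rdname preprocessing
#' @export
l2_normalize_features <- function(data) {
  data <- as_numeric_matrix(data, "data")
  nrm <- sqrt(colSums(data^2))
  zero <- nrm == 0
  if (any(zero)) {
    nm <- colnames(data) %||% as.character(seq_len(ncol(data)))
    stop("all-zero feature(s) cannot be l2-normalized: ",
         paste(nm[zero], collapse = ", "), call. = FALSE)
  }
  sweep(data, 2, nrm, "/")
}

#' Covariance of a (pre-centered) data matrix
#'
#' Computes `t(D) %*% D / (n - 1)`. Centering is deliberately *not* applied
#' here; the fit entry points center by default, and callers that want a true
#' covariance of un-centered data should call [center_features()] first.
#'
#' @param data Numeric matrix (n samples x p features), n >= 2, no NA.
#' @return Symmetric p x p covariance matrix.
#' @examples
#' compute_covariance(matrix(c(1, -1, 0, 0), 2))
#' @export
compute_covariance <- function(data) {
  data <- as_numeric_matrix(data, "data")
  if (anyNA(data)) stop("NA/NaN values are not allowed", call. = FALSE)
  if (nrow(data) < 2) {
    stop("covariance needs at least 2 samples (got ", nrow(data), ")",
         call. = FALSE)
  }
  cv <- crossprod(data) / (nrow(data) - 1)
  (cv + t(cv)) / 2
}

#' Drop features with (near-)zero variance from both conditions
#'
#' The denominator normalization of the contrastive objectives divides by
#' per-direction variance, so features with essentially no variance in the
#' pooled data create numerical instability and are excluded from both
#' conditions before fitting. A feature is dropped when its variance in the
#' row-concatenated data is at most `tol` times the largest feature variance.
#'
#' @param pair A [condition_pair()].
#' @param tol Relative variance tolerance. Default
#'   `.Machine$double.eps * p`, mirroring standard rank tolerances.
#' @return A `condition_pair` with the surviving features; the attribute
#'   `"dropped"` holds an integer vector of removed feature indices (possibly
#'   empty), named by feature.
#' @examples
#' pr <- condition_pair(cbind(rnorm(9), 1), cbind(rnorm(7), 1))
#' kept <- drop_near_zero_variance(pr)
#' attr(kept, "dropped")
#' @export
drop_near_zero_variance <- function(pair, tol = NULL) {
  stopifnot(inherits(pair, "condition_pair"))
  pooled <- rbind(pair$a, pair$b)
  v <- apply(pooled, 2, stats::var)
  if (is.null(tol)) tol <- .Machine$double.eps * ncol(pooled)
  if (tol < 0) stop("`tol` must be nonnegative", call. = FALSE)
  drop <- which(v <= tol * max(v))
  if (length(drop) == ncol(pooled)) {
    stop("all features fall below the variance tolerance", call. = FALSE)
  }
  out <- if (length(drop)) {
    condition_pair(pair$a[, -drop, drop = FALSE], pair$b[, -drop, drop = FALSE],
                   pair$feature_names[-drop])
  } else {
    pair
  }
  names(drop) <- pair$feature_names[drop]
  attr(out, "dropped") <- drop
  out
}

#' Standardize both conditions with pooled per-feature statistics
#'
#' Centers and scales every feature of both conditions using the mean and
#' standard deviation of the row-concatenated data, so each feature has unit
#' variance in the pool while the *ratio* of its variances between conditions
#' — exactly what the contrastive objectives measure — is untouched. This is
#' the recommended preprocessing when feature variances span orders of
#' magnitude (image pixels, spike counts, expression levels): it keeps the
#' near-zero-variance tail from dominating the back-projected loadings.
#' Scaling uses the pooled statistics, not per-condition ones — z-scoring
#' each condition separately would erase the very variance differences being
#' sought.
#'
#' @param pair A [condition_pair()].
#' @return A `condition_pair` with standardized features.
#' @examples
#' pr <- condition_pair(matrix(rnorm(200, sd = 9), 50), matrix(rnorm(200), 50))
#' apply(rbind(standardize_pair(pr)$a, standardize_pair(pr)$b), 2, sd)
#' @export
standardize_pair <- function(pair) {
  stopifnot(inherits(pair, "condition_pair"))
  pooled <- rbind(pair$a, pair$b)
  mu <- colMeans(pooled)
  s <- apply(pooled, 2, stats::sd)
  if (any(s == 0)) {
    nm <- pair$feature_names[s == 0]
    stop("zero pooled variance feature(s): ", paste(nm, collapse = ", "),
         " (drop them first with drop_near_zero_variance())", call. = FALSE)
  }
  tf <- function(m) sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  condition_pair(tf(pair$a), tf(pair$b), pair$feature_names)
}

# Apply the configured preprocessing chain to both conditions of a pair.
preprocess_pair <- function(pair, center = TRUE, zscore = FALSE, l2norm = FALSE) {
  f <- function(m) {
    if (zscore) m <- zscore_features(m) else if (center) m <- center_features(m)
    if (l2norm) m <- l2_normalize_features(m)
    m
  }
  condition_pair(f(pair$a), f(pair$b), pair$feature_names)
}
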