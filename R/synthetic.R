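#' Synthetic two-condition benchmark with hidden low-variance manifolds
#'
#' Generates the package's self-contained validation dataset: two conditions
#' with `n_samples` samples and 100 feature dimensions each. Most dimensions
#' are isotropic noise (orthonormalized Gaussian columns), with magnitudes on
#' a descending line from 10 (dimension 1) to 0.001 (dimension 100), so early
#' dimensions dominate the variance. Hidden in the tail, condition A carries a
#' two-dimensional "square with a square hole" manifold in dimensions 71-72
#' and condition B a "diamond" manifold in dimensions 81-82; the magnitude of
#' the manifold dimensions is doubled in their own condition. A contrastive
#' method succeeds when it identifies dimensions 71-72 as enriched in A and
#' 81-82 as enriched in B, despite their low absolute variance — a regime in
#' which the naive eigendecomposition of `C_A - C_B` fails under finite
#' sampling because sampling error in the high-variance dimensions swamps the
#' true low-variance signal.
#'
#' Construction per condition: (i) noise dimensions are independent
#' standard-Gaussian sample vectors, each l2-normalized (`orthogonalize =
#' TRUE` instead orthonormalizes them by SVD, which removes their sampling
#' correlations and with them the finite-sampling failure mode this
#' benchmark exists to exhibit); (ii) condition A fills dimensions 71-72
#' with uniform `[0, 1]` samples in which values of dimension 71 inside
#' `(0.3, 0.7)` and of dimension 72 inside `(0.4, 0.6)` are redrawn from
#' uniform `[0, 0.4]`, offsets the pair by -0.5, and sorts samples by the
#' angle `atan2(x71, x72)`; (iii) condition B fills dimensions 81-82 with
#' uniform `[0, 1]` samples sorted by dimension 81 and rotated by 45
#' degrees; (iv) each manifold column is mean-centered and l2-normalized,
#' so that — like the noise columns — its unit norm is variance, not mean
#' offset; (v) every column is scaled by its magnitude, doubled at 71-72 in
#' A and 81-82 in B, so an enriched dimension carries four-fold variance in
#' its own condition.
#'
#' Because the per-feature variances span eight orders of magnitude, fit the
#' pair after pooled standardization ([standardize_pair()]): contrast
#' indices of the form `(A - B) / (A + B)` are unchanged by per-feature
#' scaling, while loadings become interpretable per feature instead of being
#' dominated by the near-zero-variance tail.
#'
#' @param n_samples Samples per condition, at least 100 (the number of
#'   dimensions). The high-sample regime uses `1e5`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param orthogonalize Orthonormalize the noise columns (SVD left singular
#'   vectors) instead of only l2-normalizing them. Default `FALSE`; see
#'   Details.
#' @return An object of class `gcpca_truth`: list with `pair`
#'   (a [condition_pair()]), `enriched_a = 71:72`, `enriched_b = 81:82`,
#'   `magnitude_profile` (the shared descending line), `n_samples`, `seed`.
#' @examples
#' truth <- generate_benchmark_pair(200, seed = 1)
#' dim(truth$pair)
#' @export
generate_benchmark_pair <- function(n_samples = 1000, seed = 0,
                                    orthogonalize = FALSE) {
  stopifnot(n_samples >= 100)
  p <- 100L
  magnitude <- seq(10, 0.001, length.out = p)

  make_noise <- function(n) {
    g <- matrix(stats::rnorm(n * p), n, p)
    if (orthogonalize) svd(g, nv = 0)$u else l2_normalize_features(g)
  }
  unit_centered <- function(x) {
    x <- x - mean(x)
    x / sqrt(sum(x^2))
  }

  set.seed(seed)
  # condition A: square with a square hole in dims 71-72
  a <- make_noise(n_samples)
  x71 <- stats::runif(n_samples)
  hole <- x71 > 0.3 & x71 < 0.7
  x71[hole] <- stats::runif(sum(hole), 0, 0.4)
  x72 <- stats::runif(n_samples)
  hole <- x72 > 0.4 & x72 < 0.6
  x72[hole] <- stats::runif(sum(hole), 0, 0.4)
  x71 <- x71 - 0.5
  x72 <- x72 - 0.5
  ord <- order(atan2(x71, x72))
  a[, 71] <- unit_centered(x71[ord])
  a[, 72] <- unit_centered(x72[ord])
  mag_a <- magnitude
  mag_a[71:72] <- 2 * mag_a[71:72]
  a <- sweep(a, 2, mag_a, "*")

  # condition B: diamond (45-degree rotated square) in dims 81-82
  b <- make_noise(n_samples)
  x81 <- sort(stats::runif(n_samples))
  x82 <- stats::runif(n_samples)
  theta <- pi / 4
  b[, 81] <- unit_centered(x81 * cos(theta) - x82 * sin(theta))
  b[, 82] <- unit_centered(x81 * sin(theta) + x82 * cos(theta))
  mag_b <- magnitude
  mag_b[81:82] <- 2 * mag_b[81:82]
  b <- sweep(b, 2, mag_b, "*")

  structure(
    list(pair = condition_pair(a, b, paste0("dim", seq_len(p))),
         enriched_a = 71:72, enriched_b = 81:82,
         magnitude_profile = magnitude, n_samples = n_samples, seed = seed),
    class = "gcpca_truth"
  )
}

#' @export
print.gcpca_truth <- function(x, ...) {
  cat("<gcpca_truth> synthetic benchmark pair, n =", x$n_samples,
      ", seed =", x$seed, "\n")
  cat("  enriched in A:", paste(x$enriched_a, collapse = ", "),
      "| enriched in B:", paste(x$enriched_b, collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted variance of (possibly correlated) component scores
#'
#' The naive per-component variance `diag(Z'Z)` over-counts variance shared
#' between correlated score columns. The QR-based correction decomposes
#' `Z = QR` and credits component `i` with `sum_j R[i, j]^2` (`method =
#' "row"`, the default), so each unit of variance is counted once; a
#' duplicated column receives ~0. `method = "diagonal"` uses `R[i, i]^2`,
#' the variant common in the sparse-PCA literature; it credits each
#' component only with variance not explained by earlier ones, so its total
#' can fall below the scores' squared Frobenius norm, which the row method
#' conserves exactly.
#'
#' @param scores Numeric matrix of component scores, rows >= columns.
#' @param method `"row"` or `"diagonal"` (see above).
#' @return Numeric vector of adjusted variances (sums of squares), one per
#'   column.
#' @examples
#' z <- cbind(c(1, -1, 0), c(0, 1, -1))
#' adjusted_variance(cbind(z, z[, 1]))  # duplicate column gets ~0
#' @export
adjusted_variance <- function(scores, method = c("row", "diagonal")) {
  method <- match.arg(method)
  scores <- as_numeric_matrix(scores, "scores")
  if (nrow(scores) < ncol(scores)) {
    stop("`scores` needs at least as many rows as columns", call. = FALSE)
  }
  r <- qr.R(qr(scores))
  switch(method,
         row = rowSums(r^2),
         diagonal = diag(r)^2)
}

#' Ground-truth recovery score on the synthetic benchmark
#'
#' For the `n_top_components` components with the largest eigenvalues,
#' records the feature with the largest absolute loading on each, and
#' reports the fraction of those peak features that belong to the
#' condition-A enriched set. For symmetric variants the same check runs on
#' the components with the smallest (most negative) eigenvalues against the
#' condition-B enriched set. A score of 1 on both sides is perfect recovery.
#'
#' @param model A `gcpca_fit` fitted on `truth$pair`.
#' @param truth A `gcpca_truth` from [generate_benchmark_pair()].
#' @param n_top_components Components examined per side. Default 2.
#' @return A tibble with columns `side` (`"A"`, and `"B"` for symmetric
#'   variants), `peak_features` (list column) and `recovery` in `[0, 1]`.
#' @export
recovery_score <- function(model, truth, n_top_components = 2) {
  stopifnot(inherits(model, "gcpca_fit"), inherits(truth, "gcpca_truth"))
  k <- ncol(model$loadings)
  n_top <- min(n_top_components, k)
  peak <- function(cols) {
    vapply(cols, function(i) which.max(abs(model$loadings[, i])), integer(1))
  }
  top_peaks <- peak(seq_len(n_top))
  out <- tibble::tibble(
    side = "A",
    peak_features = list(top_peaks),
    recovery = mean(top_peaks %in% truth$enriched_a)
  )
  if (isTRUE(model$variant$symmetric)) {
    bottom_peaks <- peak(seq(k - n_top + 1, k))
    out <- dplyr::bind_rows(out, tibble::tibble(
      side = "B",
      peak_features = list(bottom_peaks),
      recovery = mean(bottom_peaks %in% truth$enriched_b)
    ))
  }
  out
}
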