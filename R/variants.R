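#' Contrastive variant specifications
#'
#' The toolbox solves a family of covariance-contrast objectives. Each variant
#' maximizes a Rayleigh quotient `x' N x / x' D x` over unit vectors `x`,
#' where the numerator `N` and denominator `D` are built from the condition
#' covariances `C_A` and `C_B`:
#'
#' * `v1` — classic contrastive PCA: `N = C_A - alpha * C_B`, `D = I`
#'   (requires the `alpha` hyperparameter; eigenvalues unbounded).
#' * `v2` — variance ratio `A / B`: `N = C_A`, `D = C_B`
#'   (eigenvalues in `[0, Inf)`, enriched-in-A directions have values > 1).
#' * `v3` — relative change `(A - B) / B`: `N = C_A - C_B`, `D = C_B`
#'   (eigenvalues in `[-1, Inf)`, enriched-in-A directions have values > 0).
#' * `v4` — symmetric index `(A - B) / (A + B)`: `N = C_A - C_B`,
#'   `D = C_A + C_B` (eigenvalues in `[-1, 1]`; swapping A and B flips signs).
#'
#' The `.1` suffixed variants (`v2.1`, `v3.1`, `v4.1`) solve the same
#' objectives under a feature-space orthogonality constraint (see
#' [fit_gcpca()]); they cannot be combined with sparsity.
#'
#' @param name One of `"v1"`, `"v2"`, `"v2.1"`, `"v3"`, `"v3.1"`, `"v4"`,
#'   `"v4.1"`.
#' @param alpha Positive weight on `C_B`, required for (and only valid with)
#'   `v1`.
#' @return A list of class `gcpca_variant` describing the objective.
#' @examples
#' gcpca_variant("v4")
#' gcpca_variant("v1", alpha = 2)
#' @export
gcpca_variant <- function(name = c("v4", "v1", "v2", "v2.1", "v3", "v3.1", "v4.1"),
                          alpha = NULL) {
  name <- match.arg(name)
  if (name == "v1" && is.null(alpha)) {
    stop("variant v1 (contrastive PCA) requires `alpha`", call. = FALSE)
  }
  if (name != "v1" && !is.null(alpha)) {
    stop("`alpha` only applies to variant v1", call. = FALSE)
  }
  if (!is.null(alpha) && (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)) {
    stop("`alpha` must be a single nonnegative number", call. = FALSE)
  }
  base <- sub("\\.1$", "", name)
  structure(
    list(
      name = name,
      base = base,
      numerator_rule = switch(base, v2 = "A", "A-B"),
      denominator_rule = switch(base, v1 = "identity-with-alpha",
                                v2 = , v3 = "B", v4 = "A+B"),
      symmetric = base == "v4",
      orthogonal = grepl("\\.1$", name),
      alpha = alpha
    ),
    class = "gcpca_variant"
  )
}

#' @export
print.gcpca_variant <- function(x, ...) {
  obj <- switch(x$base,
    v1 = sprintf("x'(C_A - %g C_B)x", x$alpha),
    v2 = "x'C_A x / x'C_B x",
    v3 = "x'(C_A - C_B)x / x'C_B x",
    v4 = "x'(C_A - C_B)x / x'(C_A + C_B)x")
  cat("<gcpca_variant> ", x$name, ": maximize ", obj,
      if (x$orthogonal) "  [feature-space orthogonal]" else "", "\n", sep = "")
  invisible(x)
}

as_gcpca_variant <- function(variant, alpha = NULL) {
  if (inherits(variant, "gcpca_variant")) return(variant)
  gcpca_variant(variant, alpha = alpha)
}

# Numerator / denominator matrices in feature space for a variant.
variant_matrices <- function(variant, cov_a, cov_b) {
  num <- switch(variant$base,
    v1 = cov_a - variant$alpha * cov_b,
    v2 = cov_a,
    cov_a - cov_b)
  den <- switch(variant$base,
    v1 = NULL,
    v2 = , v3 = cov_b,
    v4 = cov_a + cov_b)
  list(numerator = num, denominator = den)
}
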