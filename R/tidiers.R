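#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a contrastive fit into a loadings table
#'
#' @param x A `gcpca_fit`.
#' @param matrix `"loadings"` (long tibble of feature loadings, default) or
#'   `"eigenvalues"` (one row per component).
#' @param ... Unused.
#' @return A tibble. For `"loadings"`: columns `feature`, `component`
#'   (integer), `loading`. For `"eigenvalues"`: `component`, `eigenvalue`,
#'   and `nonzero` for sparse fits.
#' @export
tidy.gcpca_fit <- function(x, matrix = c("loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    out <- tibble::tibble(component = seq_along(x$eigenvalues),
                          eigenvalue = x$eigenvalues)
    if (!is.null(x$sparsity)) out$nonzero <- x$sparsity$nonzero
    return(out)
  }
  ld <- tibble::as_tibble(x$loadings)
  ld$feature <- x$feature_names
  out <- tidyr::pivot_longer(ld, -"feature", names_to = "component",
                             values_to = "loading")
  out$component <- as.integer(sub("^gcPC", "", out$component))
  out[, c("feature", "component", "loading")]
}

#' One-row summary of a contrastive fit
#'
#' @param x A `gcpca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `n_features`, `n_components`,
#'   `rank_k`, `eigenvalue_max`, `eigenvalue_min`, `alpha` (NA unless v1),
#'   `sparse`.
#' @export
glance.gcpca_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant$name,
    n_features = nrow(x$loadings),
    n_components = ncol(x$loadings),
    rank_k = x$rank_k,
    eigenvalue_max = max(x$eigenvalues, na.rm = TRUE),
    eigenvalue_min = min(x$eigenvalues, na.rm = TRUE),
    alpha = x$variant$alpha %||% NA_real_,
    sparse = !is.null(x$sparsity)
  )
}

#' Attach component scores to a dataset
#'
#' @param x A `gcpca_fit`.
#' @param data Matrix or data frame on the fitted feature set.
#' @param ... Unused.
#' @return `data` as a tibble with score columns `.gcPC1`, `.gcPC2`, ...
#'   appended.
#' @export
augment.gcpca_fit <- function(x, data, ...) {
  scores <- gcpca_transform(x, data)
  names(scores) <- paste0(".", names(scores))
  dplyr::bind_cols(tibble::as_tibble(as.data.frame(data)), scores)
}
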