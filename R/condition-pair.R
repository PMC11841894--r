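#' Pair two condition datasets on a shared feature set
#'
#' A `condition_pair` holds the two samples-by-features matrices being
#' contrasted: condition A (the "foreground" for asymmetric variants) and
#' condition B (the "background", or an equal partner for the symmetric
#' variant). Both must have the same features in the same order.
#'
#' @param a,b Numeric matrices or data frames, samples in rows and features in
#'   columns. Column counts must match; `NA`/`NaN` values are rejected.
#' @param feature_names Optional character vector of feature names (length =
#'   number of columns). Defaults to the column names of `a` (or `b`), or
#'   `"V1"..."Vp"` when neither has any.
#'
#' @return An object of class `condition_pair`: a list with elements `a`, `b`
#'   (numeric matrices) and `feature_names`.
#' @examples
#' pair <- condition_pair(matrix(rnorm(40), 10), matrix(rnorm(32), 8))
#' pair
#' @export
condition_pair <- function(a, b, feature_names = NULL) {
  a <- as_numeric_matrix(a, "a")
  b <- as_numeric_matrix(b, "b")
  if (ncol(a) != ncol(b)) {
    stop("conditions `a` and `b` must share the same feature count (",
         ncol(a), " vs ", ncol(b), ")", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) {
    stop("NA/NaN values are not allowed in condition data", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(a) %||% colnames(b) %||% paste0("V", seq_len(ncol(a)))
  }
  if (length(feature_names) != ncol(a)) {
    stop("`feature_names` must have length ", ncol(a), call. = FALSE)
  }
  colnames(a) <- colnames(b) <- feature_names
  structure(list(a = a, b = b, feature_names = feature_names),
            class = "condition_pair")
}

as_numeric_matrix <- function(x, arg) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric columns in `", arg, "`: ",
           paste(names(x)[bad], collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", arg, "` must be a numeric matrix or all-numeric data frame",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.condition_pair <- function(x, ...) {
  cat("<condition_pair>\n")
  cat("  condition A:", nrow(x$a), "samples x", ncol(x$a), "features\n")
  cat("  condition B:", nrow(x$b), "samples x", ncol(x$b), "features\n")
  invisible(x)
}

#' @export
dim.condition_pair <- function(x) {
  c(n_a = nrow(x$a), n_b = nrow(x$b), p = ncol(x$a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
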