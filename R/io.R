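#' Read a samples-by-features matrix from delimited text or Matrix Market
#'
#' Dense input: comma- or tab-separated text, with an optional header row of
#' feature names (detected automatically: a first line with any non-numeric
#' token is treated as a header). Sparse input: Matrix Market coordinate
#' format (`.mtx`), densified on load.
#'
#' @param path File path; format chosen by extension (`.csv`, `.tsv`/`.txt`,
#'   `.mtx`).
#' @return Numeric matrix, with column names when a header was present.
#' @export
read_condition_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    return(as.matrix(Matrix::readMM(path)))
  }
  sep <- if (ext == "csv") "," else "\t"
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  as_numeric_matrix(df, "file contents")
}

#' Write a matrix in a format [read_condition_matrix()] can load
#'
#' @param data Numeric matrix or data frame.
#' @param path Destination; `.csv`, `.tsv`/`.txt` or `.mtx` by extension.
#' @param col_names Write a header row (dense formats only). Default `TRUE`
#'   when `data` has column names.
#' @return `path`, invisibly.
#' @export
write_condition_matrix <- function(data, path, col_names = !is.null(colnames(data))) {
  data <- as_numeric_matrix(data, "data")
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(data), "CsparseMatrix"),
                                "generalMatrix"), path)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(data, path, sep = sep, row.names = FALSE,
                       col.names = col_names, quote = FALSE)
  }
  invisible(path)
}

#' Read two condition files into a condition pair
#'
#' @param path_a,path_b Paths for conditions A and B (any format supported by
#'   [read_condition_matrix()]).
#' @return A [condition_pair()].
#' @export
read_condition_pair <- function(path_a, path_b) {
  condition_pair(read_condition_matrix(path_a), read_condition_matrix(path_b))
}

#' Serialize a fitted model to a directory
#'
#' Writes `loadings.csv` (feature column plus one column per component),
#' `eigenvalues.csv`, and `metadata.json` (variant, alpha, rank, preprocessing
#' flags, and the sparsity report for sparse fits).
#'
#' @param model A `gcpca_fit`.
#' @param dir Output directory, created if needed.
#' @param metadata Named list merged into `metadata.json` (e.g. preprocessing
#'   flags used upstream).
#' @return `dir`, invisibly.
#' @export
write_gcpca <- function(model, dir, metadata = list()) {
  stopifnot(inherits(model, "gcpca_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ld <- data.frame(feature = model$feature_names, model$loadings,
                   check.names = FALSE)
  utils::write.table(ld, file.path(dir, "loadings.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  ev <- data.frame(component = seq_along(model$eigenvalues),
                   eigenvalue = model$eigenvalues)
  utils::write.table(ev, file.path(dir, "eigenvalues.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  meta <- c(list(variant = model$variant$name,
                 alpha = model$variant$alpha,
                 orthogonal = model$variant$orthogonal,
                 n_features = nrow(model$loadings),
                 n_components = ncol(model$loadings),
                 rank_k = model$rank_k),
            if (!is.null(model$sparsity)) list(sparsity = model$sparsity),
            metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
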