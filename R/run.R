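#' Validated run configuration
#'
#' Bundles and cross-checks the options of an end-to-end run: the variant
#' must agree with its parameters (`alpha` if and only if `v1`; sparse
#' penalties only in sparse mode; orthogonality only via the `.1` variants).
#'
#' @param variant Variant name (see [gcpca_variant()]).
#' @param file_a,file_b Input paths for conditions A and B (any format
#'   supported by [read_condition_matrix()]); may be `NULL` for
#'   [run_benchmark()].
#' @param out_dir Output directory.
#' @param alpha Alpha for `v1`.
#' @param sparse Logical; fit the sparse variant.
#' @param lasso_lambda,ridge_kappa Sparse penalties (required/allowed only
#'   when `sparse = TRUE`).
#' @param n_components Components to return (default: full shared rank).
#' @param center,zscore,l2norm Preprocessing flags.
#' @param rank_tol Shared-basis rank tolerance.
#' @param drop_tol Near-zero-variance drop tolerance (`NULL` = default).
#' @param seed Integer seed used wherever randomness is involved.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = "v4", file_a = NULL, file_b = NULL,
                       out_dir = ".", alpha = NULL, sparse = FALSE,
                       lasso_lambda = NULL, ridge_kappa = 1e-4,
                       n_components = NULL, center = TRUE, zscore = FALSE,
                       l2norm = FALSE, rank_tol = 1e-10, drop_tol = NULL,
                       seed = 0) {
  vs <- as_gcpca_variant(variant, alpha = alpha)  # validates alpha <=> v1
  if (sparse && vs$orthogonal) {
    stop("sparse mode cannot be combined with the orthogonal variants",
         call. = FALSE)
  }
  if (sparse && is.null(lasso_lambda)) {
    stop("sparse mode requires `lasso_lambda`", call. = FALSE)
  }
  if (!sparse && !is.null(lasso_lambda)) {
    stop("`lasso_lambda` only applies in sparse mode", call. = FALSE)
  }
  structure(list(variant = vs, file_a = file_a, file_b = file_b,
                 out_dir = out_dir, sparse = sparse,
                 lasso_lambda = lasso_lambda, ridge_kappa = ridge_kappa,
                 n_components = n_components, center = center,
                 zscore = zscore, l2norm = l2norm, rank_tol = rank_tol,
                 drop_tol = drop_tol, seed = seed),
            class = "run_config")
}

#' Fit from files and write all artifacts
#'
#' Loads the two condition matrices, drops near-zero-variance features,
#' fits the configured (dense, orthogonal, or sparse) variant, and writes
#' loadings, eigenvalues, scores for both conditions, metadata, and — in
#' sparse mode — the ranked feature table, into `config$out_dir`.
#'
#' @param config A [run_config()] with `file_a` and `file_b` set.
#' @return The fitted `gcpca_fit`, invisibly.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$file_a) || is.null(config$file_b)) {
    stop("run_fit() needs `file_a` and `file_b` in the config", call. = FALSE)
  }
  pair <- read_condition_pair(config$file_a, config$file_b)
  pair <- drop_near_zero_variance(pair, tol = config$drop_tol)
  dropped <- attr(pair, "dropped")
  if (length(dropped)) {
    message("dropped ", length(dropped), " near-zero-variance feature(s): ",
            paste(names(dropped), collapse = ", "))
  }
  fit <- if (config$sparse) {
    fit_sparse_gcpca(pair, config$variant,
                     lasso_lambda = config$lasso_lambda,
                     ridge_kappa = config$ridge_kappa,
                     n_components = config$n_components,
                     center = config$center, zscore = config$zscore,
                     l2norm = config$l2norm, rank_tol = config$rank_tol)
  } else {
    fit_gcpca(pair, config$variant, n_components = config$n_components,
              center = config$center, zscore = config$zscore,
              l2norm = config$l2norm, rank_tol = config$rank_tol)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gcpca(fit, config$out_dir,
              metadata = list(center = config$center, zscore = config$zscore,
                              l2norm = config$l2norm, seed = config$seed,
                              dropped_features = as.list(names(dropped))))
  utils::write.table(gcpca_transform(fit, pair$a),
                     file.path(config$out_dir, "scores_a.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(gcpca_transform(fit, pair$b),
                     file.path(config$out_dir, "scores_b.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (config$sparse) {
    utils::write.table(rank_features(fit),
                       file.path(config$out_dir, "feature_ranking.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(fit)
}

#' Run the synthetic recovery benchmark
#'
#' Generates the synthetic manifold pair (see [generate_benchmark_pair()])
#' for each seed, applies pooled standardization ([standardize_pair()] — the
#' recommended workflow for this wide-dynamic-range design), fits the
#' requested methods, and tabulates the ground-truth recovery of each.
#' Methods are given as variant names, with cPCA entries written
#' `"cpca:<alpha>"` (e.g. `"cpca:2"`).
#'
#' @param n_samples Samples per condition. Default 1000 (the finite-sampling
#'   regime).
#' @param seeds Integer vector of generator seeds. Default `0:9`.
#' @param methods Character vector of methods. Default
#'   `c("v4", "cpca:2", "cpca:0")`.
#' @param n_top_components Components per side scored for recovery.
#' @param out_dir Optional directory; when set, the report is written to
#'   `benchmark.csv` there.
#' @return A tibble with one row per method x seed x side: columns `method`,
#'   `seed`, `side`, `recovery`.
#' @export
run_benchmark <- function(n_samples = 1000, seeds = 0:9,
                          methods = c("v4", "cpca:2", "cpca:0"),
                          n_top_components = 2, out_dir = NULL) {
  rows <- list()
  for (seed in seeds) {
    truth <- generate_benchmark_pair(n_samples, seed = seed)
    std <- standardize_pair(truth$pair)
    for (m in methods) {
      # cPCA contrasts absolute variances and is run on the raw pair, as in
      # the benchmark's design; the gcPCA objectives are scale-invariant per
      # feature and use the standardized pair.
      fit <- if (startsWith(m, "cpca:")) {
        fit_cpca(truth$pair, alpha = as.numeric(sub("^cpca:", "", m)))
      } else {
        fit_gcpca(std, m)
      }
      rec <- recovery_score(fit, truth, n_top_components = n_top_components)
      rec$method <- m
      rec$seed <- seed
      rows[[length(rows) + 1]] <- rec[, c("method", "seed", "side", "recovery")]
    }
  }
  report <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "benchmark.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  report
}
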