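test_that("matrix formats round-trip through disk", {
  set.seed(81)
  m <- matrix(rnorm(60), 12, 5)
  colnames(m) <- paste0("f", 1:5)
  for (ext in c("csv", "tsv", "mtx")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_condition_matrix(m, path)
    back <- read_condition_matrix(path)
    expect_lt(max(abs(back - m)), 1e-12)
    if (ext != "mtx") expect_equal(colnames(back), colnames(m))
  }
  # headerless files load too
  path <- withr::local_tempfile(fileext = ".csv")
  write_condition_matrix(unname(m), path, col_names = FALSE)
  expect_lt(max(abs(read_condition_matrix(path) - m)), 1e-12)
})

test_that("run_config enforces variant-parameter consistency", {
  expect_error(run_config(variant = "v1"), "alpha")
  expect_error(run_config(variant = "v4", alpha = 2), "only applies")
  expect_error(run_config(variant = "v4", sparse = TRUE), "lasso_lambda")
  expect_error(run_config(variant = "v4.1", sparse = TRUE, lasso_lambda = 1),
               "orthogonal")
  expect_error(run_config(variant = "v4", lasso_lambda = 1), "sparse mode")
  cfg <- run_config(variant = "v1", alpha = 2)
  expect_s3_class(cfg, "run_config")
})

test_that("run_fit writes a complete, deterministic artifact set", {
  dir <- withr::local_tempdir()
  truth <- generate_benchmark_pair(200, seed = 7)
  fa <- file.path(dir, "a.csv"); fb <- file.path(dir, "b.csv")
  write_condition_matrix(truth$pair$a, fa)
  write_condition_matrix(truth$pair$b, fb)

  out1 <- file.path(dir, "out1")
  fit <- run_fit(run_config(variant = "v4", file_a = fa, file_b = fb,
                            out_dir = out1))
  expect_true(all(c("loadings.csv", "eigenvalues.csv", "metadata.json",
                    "scores_a.csv", "scores_b.csv") %in% list.files(out1)))
  ld <- utils::read.csv(file.path(out1, "loadings.csv"), check.names = FALSE)
  expect_equal(nrow(ld), 100)
  meta <- jsonlite::read_json(file.path(out1, "metadata.json"))
  expect_equal(meta$variant, "v4")

  out2 <- file.path(dir, "out2")
  run_fit(run_config(variant = "v4", file_a = fa, file_b = fb,
                     out_dir = out2))
  expect_identical(readLines(file.path(out1, "eigenvalues.csv")),
                   readLines(file.path(out2, "eigenvalues.csv")))

  # sparse mode adds the ranked feature table
  out3 <- file.path(dir, "out3")
  run_fit(run_config(variant = "v4", file_a = fa, file_b = fb, out_dir = out3,
                     sparse = TRUE, lasso_lambda = 0.5, n_components = 4))
  expect_true(file.exists(file.path(out3, "feature_ranking.csv")))
})

test_that("run_benchmark reports recovery per method and seed", {
  report <- run_benchmark(n_samples = 1000, seeds = 0:1,
                          methods = c("v4", "cpca:0"))
  # v4 contributes A and B rows, cpca only A
  expect_equal(nrow(report), 2 * 3)
  v4 <- report[report$method == "v4", ]
  expect_true(all(v4$recovery == 1))
  pca_rows <- report[report$method == "cpca:0", ]
  expect_true(all(pca_rows$recovery == 0))
})

test_that("tidiers and plots expose the fit", {
  pr <- random_pair(40, 4, seed = 82)
  fit <- fit_gcpca(pr, "v4")
  td <- tidy(fit)
  expect_equal(nrow(td), 4 * 4)
  expect_named(td, c("feature", "component", "loading"))
  ev <- tidy(fit, matrix = "eigenvalues")
  expect_equal(ev$eigenvalue, fit$eigenvalues)
  gl <- glance(fit)
  expect_equal(gl$variant, "v4")
  expect_false(gl$sparse)
  au <- augment(fit, pr$a)
  expect_equal(ncol(au), 4 + 4)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_loadings(fit), "ggplot")
  expect_s3_class(plot_scores(fit, pr), "ggplot")
})

test_that("serialized models keep variant metadata and sparsity report", {
  dir <- withr::local_tempdir()
  pr <- random_pair(50, 4, seed = 83)
  sp <- fit_sparse_gcpca(pr, "v4", lasso_lambda = 0.5, n_components = 2)
  write_gcpca(sp, dir)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$variant, "v4")
  expect_equal(meta$sparsity$lasso_lambda, 0.5)
  expect_length(meta$sparsity$nonzero, 2)
})
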