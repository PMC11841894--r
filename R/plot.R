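#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Eigenvalue spectrum of a contrastive fit
#'
#' @param object A `gcpca_fit`.
#' @param ... Unused.
#' @return A ggplot: eigenvalue against component index. For the symmetric
#'   variant, values above 0 indicate A-enriched directions and values below
#'   0 B-enriched ones.
#' @export
autoplot.gcpca_fit <- function(object, ...) {
  df <- tidy(object, matrix = "eigenvalues")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "component", y = "eigenvalue",
                  title = paste("Contrast spectrum,", object$variant$name)) +
    ggplot2::theme_minimal()
}

#' Feature loadings of selected components
#'
#' @param model A `gcpca_fit`.
#' @param components Component indices to draw. Default `1:2`.
#' @return A ggplot of loading against feature index, one panel per
#'   component.
#' @export
plot_loadings <- function(model, components = 1:2) {
  df <- tidy(model)
  df <- df[df$component %in% components, ]
  df$feature_index <- match(df$feature, model$feature_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_index,
                                   y = .data$loading)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "feature index", y = "loading") +
    ggplot2::theme_minimal()
}

#' Scatter of both conditions in a component plane
#'
#' @param model A `gcpca_fit`.
#' @param pair The [condition_pair()] to project (typically the one the model
#'   was fitted on).
#' @param components Two component indices. Default `c(1, 2)`.
#' @return A ggplot scatter of scores, coloured by condition.
#' @export
plot_scores <- function(model, pair, components = c(1, 2)) {
  stopifnot(length(components) == 2, inherits(pair, "condition_pair"))
  sa <- gcpca_transform(model, pair$a)[, components]
  sb <- gcpca_transform(model, pair$b)[, components]
  names(sa) <- names(sb) <- c("x", "y")
  df <- dplyr::bind_rows(A = sa, B = sb, .id = "condition")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = paste0("gcPC", components[1]),
                  y = paste0("gcPC", components[2])) +
    ggplot2::theme_minimal()
}
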