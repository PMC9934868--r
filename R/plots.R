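#' Plot a cluster assignment on a PCA embedding
#'
#' Scatter of the first two principal components of the feature table,
#' coloured by cluster. This is a quick-look projection, not the
#' fuzzy-graph used for clustering.
#'
#' @param object a `cluster_assignment`.
#' @param features the feature tibble the clustering was computed on.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cluster_assignment <- function(object, features, ...) {
  X <- as.matrix(features[, setdiff(names(features), "cell_id")])
  pc <- stats::prcomp(X, rank. = 2)
  df <- tibble::tibble(
    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
    cluster = factor(object$assignment$cluster[
      match(features$cell_id, object$assignment$cell_id)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$cluster)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(title = sprintf("Leiden/CPM clusters (resolution %g)",
                                  object$params$resolution)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a classification result
#'
#' Rows are the true labels, columns the predictions, summed over folds.
#'
#' @param object a `morphotype_classification`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.morphotype_classification <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("label", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$label,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Morphotype confusion (mean accuracy %.2f)",
                                  object$mean_accuracy),
                  y = "label (truth)", x = "prediction") +
    ggplot2::theme_minimal()
}

#' Specificity dot plot
#'
#' The cluster-by-variable dot plot used for gene and feature enrichment:
#' dot size encodes the within-cluster mean `A`, colour the in-cluster
#' share `B`; rows are the variables that pass the specificity threshold.
#'
#' @param records specificity tibble from [gene_specificity()] /
#'   [feature_specificity()] (typically pre-filtered with
#'   [select_specific()]).
#' @return A ggplot.
#' @export
plot_specificity_dots <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(factor(.data$cluster), .data$variable,
                               size = .data$A, colour = .data$B)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "cluster", y = NULL, size = "A (mean)", colour = "B (share)") +
    ggplot2::theme_minimal()
}

#' Training-curve plot
#'
#' @param checkpoint a checkpoint from [train_shape()] / [train_texture()].
#' @return A ggplot of loss against iteration.
#' @export
plot_training_curve <- function(checkpoint) {
  log <- checkpoint$log
  ycol <- if ("total" %in% names(log)) "total" else "loss"
  ggplot2::ggplot(log, ggplot2::aes(.data$iteration, .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss") +
    ggplot2::theme_minimal()
}
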