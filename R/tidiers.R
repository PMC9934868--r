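#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style accessors for fitted/result objects
#'
#' `tidy()` returns the per-unit results (per fold, per cell); `glance()`
#' a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.morphotype_classification <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracy), accuracy = x$fold_accuracy)
}

#' @rdname tidiers
#' @export
glance.morphotype_classification <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$fold_accuracy),
                 n_folds = length(x$fold_accuracy),
                 n_classes = nrow(x$confusion))
}

#' @rdname tidiers
#' @export
tidy.bilateral_ranking <- function(x, ...) x$per_cell

#' @rdname tidiers
#' @export
glance.bilateral_ranking <- function(x, ...) {
  tibble::tibble(median_rank = x$median_rank,
                 n_cells = nrow(x$per_cell),
                 n_skipped = length(x$skipped))
}

#' @rdname tidiers
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignment

#' @rdname tidiers
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$assignment),
                 n_clusters = length(unique(x$assignment$cluster)),
                 resolution = x$params$resolution,
                 n_neighbours = x$params$n_neighbours)
}
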