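# ggplot2 figure helpers for the main result types.

#' Plot subjects in the 2-D embedding, coloured by cluster
#'
#' @param embedding Tibble from [embed_2d()].
#' @param assignment A `transdx_clusters`.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, assignment) {
  df <- dplyr::inner_join(embedding, assignment$assignments,
                          by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(colour = "cluster", x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection sweep (silhouette vs k or resolution)
#'
#' @param sweep Sweep tibble from [select_k_by_silhouette()] (column `k`)
#'   or [sweep_resolution()] (column `resolution`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  xvar <- if ("k" %in% names(sweep)) "k" else "resolution"
  ggplot2::ggplot(sweep, ggplot2::aes(.data[[xvar]], .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster category index profiles
#'
#' @param scores A `transdx_category_scores` with a cluster summary.
#' @return A ggplot heat-tile of mean category scores per cluster.
#' @export
plot_category_scores <- function(scores) {
  stopifnot(inherits(scores, "transdx_category_scores"))
  if (is.null(scores$cluster_summary)) {
    abort("category scores were computed without a cluster assignment")
  }
  ggplot2::ggplot(scores$cluster_summary,
                  ggplot2::aes(.data$category, factor(.data$cluster),
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(y = "cluster", fill = "mean score") +
    ggplot2::theme_minimal()
}

#' Plot a diagnosis-to-cluster flow table
#'
#' Renders the Sankey flow table from [diagnosis_composition()] as a
#' stacked-bar mosaic (source strata stacked within each target cluster).
#'
#' @param flows Tibble (source, target, n).
#' @return A ggplot object.
#' @export
plot_flows <- function(flows) {
  ggplot2::ggplot(dplyr::filter(flows, .data$n > 0),
                  ggplot2::aes(factor(.data$target), .data$n,
                               fill = factor(.data$source))) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "cluster", y = "subjects", fill = "stratum") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_embedding autoplot method for cluster assignments:
#'   cluster sizes as a bar chart (no embedding required).
#' @param object A `transdx_clusters`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.transdx_clusters <- function(object, ...) {
  sizes <- dplyr::count(object$assignments, .data$cluster)
  ggplot2::ggplot(sizes, ggplot2::aes(factor(.data$cluster), .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "subjects",
                  title = paste0(object$method, " cluster sizes")) +
    ggplot2::theme_minimal()
}

#' Autoplot recommendation evaluation: class recommendation frequencies
#'
#' @param object A `transdx_rec_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.transdx_rec_eval <- function(object, ...) {
  ggplot2::ggplot(object$class_frequency,
                  ggplot2::aes(.data$class, .data$share)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(y = "subjects recommended", x = "drug class") +
    ggplot2::theme_minimal()
}
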