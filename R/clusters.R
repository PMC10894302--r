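# Shared cluster-assignment container (k-means and Louvain results).

new_clusters <- function(method, subject_ids, labels, params, quality, seed) {
  stopifnot(length(subject_ids) == length(labels))
  structure(
    list(
      method = method,
      assignments = tibble::tibble(
        subject_id = subject_ids,
        cluster = as.integer(labels)
      ),
      params = params,
      quality = quality,
      seed = seed
    ),
    class = "transdx_clusters"
  )
}

# Relabel integer labels 0-based, contiguous, by descending community size
# (ties by smallest original member index: deterministic).
relabel_by_size <- function(labels) {
  f <- factor(labels, levels = unique(labels[order(labels)]))
  sizes <- table(f)
  first_member <- tapply(seq_along(labels), f, min)
  ord <- order(-as.integer(sizes), as.integer(first_member))
  new_of_old <- integer(length(sizes))
  new_of_old[ord] <- seq_along(ord) - 1L
  new_of_old[as.integer(f)]
}

#' Number of clusters in an assignment
#' @param x A `transdx_clusters`.
#' @return Integer count of distinct labels.
#' @export
n_clusters <- function(x) length(unique(x$assignments$cluster))

#' @export
print.transdx_clusters <- function(x, ...) {
  q <- x$quality
  cat("<transdx_clusters> method=", x$method, ", ",
      nrow(x$assignments), " subjects in ", n_clusters(x), " clusters",
      if (!is.null(q$silhouette) && is.finite(q$silhouette))
        sprintf(", silhouette=%.3f", q$silhouette),
      if (!is.null(q$modularity) && is.finite(q$modularity))
        sprintf(", Q=%.3f", q$modularity),
      "\n", sep = "")
  invisible(x)
}

#' Per-subject cluster labels
#'
#' @param x A `transdx_clusters`.
#' @param ... Unused.
#' @return Tibble (subject_id, method, cluster).
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_clusters <- function(x, ...) {
  dplyr::mutate(x$assignments, method = x$method, .after = "subject_id")
}

#' One-row summary of a cluster assignment
#'
#' @param x A `transdx_clusters`.
#' @param ... Unused.
#' @return Tibble with method, the fitted parameter (k or resolution),
#'   cluster count and quality metrics.
#' @export
#' @exportS3Method generics::glance
glance.transdx_clusters <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    k = x$params$k %||% NA_integer_,
    resolution = x$params$resolution %||% NA_real_,
    n_clusters = n_clusters(x),
    silhouette = x$quality$silhouette %||% NA_real_,
    modularity = x$quality$modularity %||% NA_real_,
    seed = x$seed
  )
}

#' Write a cluster assignment to a TSV file
#'
#' @param x A `transdx_clusters`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignment <- function(x, path) {
  write_table_auto(tidy(x), path)
}
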