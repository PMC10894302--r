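# Louvain community detection on the subject similarity graph.
#
# Louvain greedily maximizes modularity Q (the fraction of edges inside
# communities minus its expectation under a degree-preserving null) through
# repeated local-move and node-aggregation passes; the resolution parameter
# scales the null term, with larger values favouring more, smaller
# communities. Disconnected graphs are handled per component.

#' Partition a similarity graph by Louvain community detection
#'
#' Deterministic given `seed`. Community labels are relabeled contiguously
#' from 0 by descending community size. The recorded modularity is the
#' standard (resolution-1) Q of the final partition, so it is directly
#' comparable across resolutions.
#'
#' @param g A `transdx_graph`.
#' @param resolution Resolution parameter gamma > 0 (default 1).
#' @param seed Integer seed.
#' @return A `transdx_clusters` with modularity recorded; the number of
#'   graph components is reported via a message when greater than 1.
#' @export
louvain_partition <- function(g, resolution = 1, seed = 1) {
  stopifnot(inherits(g, "transdx_graph"))
  if (igraph::vcount(g$graph) == 0) abort("graph is empty")
  if (!is.numeric(resolution) || resolution <= 0) {
    abort("resolution must be > 0")
  }
  n_comp <- igraph::count_components(g$graph)
  if (n_comp > 1) {
    inform(paste0("graph has ", n_comp,
                  " components; communities are detected per component"))
  }
  weights <- if (g$weighted) igraph::E(g$graph)$weight else NULL
  membership <- if (igraph::ecount(g$graph) == 0) {
    warn("graph has no edges; every node is its own community")
    seq_len(igraph::vcount(g$graph))
  } else {
    comm <- with_seed(seed, igraph::cluster_louvain(
      g$graph, weights = weights, resolution = resolution))
    igraph::membership(comm)
  }
  q <- if (igraph::ecount(g$graph) == 0) 0 else {
    igraph::modularity(g$graph, membership, weights = weights)
  }
  new_clusters(
    method = "louvain",
    subject_ids = g$subject_ids,
    labels = relabel_by_size(as.integer(membership)),
    params = list(resolution = resolution, k_nn = g$k_nn, p = g$p),
    quality = list(modularity = q, silhouette = NA_real_),
    seed = seed
  )
}

#' Sweep the Louvain resolution and select by feature-space silhouette
#'
#' Partitions the graph at every resolution in `grid` and scores each
#' partition by its mean silhouette in (standardized) feature space — the
#' same yardstick used to size k-means — selecting the resolution with the
#' highest silhouette; ties (within 1e-12) break toward fewer communities.
#' Selection by maximum modularity is available via `select = "modularity"`.
#'
#' @param g A `transdx_graph`.
#' @param fm The `transdx_features` the graph was built from.
#' @param grid Numeric vector of resolutions (> 0).
#' @param seed Integer seed.
#' @param select `"silhouette"` (default) or `"modularity"`.
#' @param sample_n Silhouette subsample cap.
#' @return List with `best` (`transdx_clusters`, silhouette recorded) and
#'   `sweep` (tibble resolution, n_communities, modularity, silhouette).
#' @export
sweep_resolution <- function(g, fm, grid, seed = 1,
                             select = c("silhouette", "modularity"),
                             sample_n = 10000) {
  select <- match.arg(select)
  if (!length(grid)) abort("resolution grid is empty")
  grid <- sort(unique(as.numeric(grid)))
  n <- nrow(fm$values)
  idx <- silhouette_subsample(n, sample_n, seed)
  d <- dist(fm$values[idx, , drop = FALSE])
  fits <- lapply(grid, function(gamma) {
    fit <- louvain_partition(g, resolution = gamma, seed = seed)
    fit$quality$silhouette <-
      mean_silhouette(d, fit$assignments$cluster[idx])
    fit
  })
  sweep_tbl <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      resolution = f$params$resolution,
      n_communities = n_clusters(f),
      modularity = f$quality$modularity,
      silhouette = f$quality$silhouette
    )
  })
  score <- sweep_tbl[[select]]
  cand <- which(score >= max(score) - 1e-12)
  best_i <- cand[order(sweep_tbl$n_communities[cand],
                       sweep_tbl$resolution[cand])][1]
  list(best = fits[[best_i]], sweep = sweep_tbl)
}
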