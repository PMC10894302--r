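# Subject similarity graph: k-nearest neighbours under Minkowski distance.

#' Build a k-nearest-neighbour similarity graph over subjects
#'
#' Each subject is linked to its `k_nn` nearest neighbours under the
#' Minkowski-`p` distance in feature space (p = 2 gives Euclidean, matching
#' the k-means metric). The directed neighbour lists are symmetrized into an
#' undirected simple graph; with the default `"union"` rule every node keeps
#' at least `k_nn` incident edges, the standard substrate for community
#' detection (`"mutual"` keeps only reciprocated pairs). Distance ties at
#' the `k_nn`-th rank break by subject order (row order of the feature
#' matrix); ties are detected at 10 significant digits so the rule does not
#' depend on floating-point summation order.
#'
#' @param fm A `transdx_features`.
#' @param k_nn Neighbours per node (default 100).
#' @param p Minkowski order (default 2).
#' @param symmetrize `"union"` (default) or `"mutual"`.
#' @param weighted If `TRUE`, edges carry weight `1 / (1 + d)`; default
#'   unweighted binary adjacency.
#' @return A `transdx_graph` wrapping an igraph object whose vertex names
#'   are subject ids.
#' @export
build_knn_graph <- function(fm, k_nn = 100, p = 2,
                            symmetrize = c("union", "mutual"),
                            weighted = FALSE) {
  stopifnot(inherits(fm, "transdx_features"))
  symmetrize <- match.arg(symmetrize)
  x <- fm$values
  n <- nrow(x)
  k_nn <- stopifnot_scalar_int(k_nn, "k_nn", lower = 1)
  if (k_nn >= n) {
    abort(paste0("k_nn (", k_nn, ") must be < number of subjects (", n, ")"))
  }
  if (!is.numeric(p) || p < 1) abort("Minkowski order p must be >= 1")

  d <- minkowski_matrix(x, p)
  # tie detection must not depend on floating-point accumulator noise:
  # mathematically equal distances agree to ~15 significant digits however
  # they are summed, so ranking on 10 makes the subject-order tie rule exact
  d <- signif(d, 10)
  diag(d) <- Inf
  nb <- matrix(0L, n, k_nn)
  for (i in seq_len(n)) {
    nb[i, ] <- order(d[i, ], seq_len(n))[seq_len(k_nn)]
  }
  from <- rep(seq_len(n), k_nn)
  to <- as.vector(nb)
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b)
  if (symmetrize == "union") {
    keep <- !duplicated(key)
  } else {
    keep <- duplicated(key)  # second sighting = reciprocated pair
  }
  edges <- tibble::tibble(
    from = fm$subject_ids[a[keep]],
    to = fm$subject_ids[b[keep]]
  )
  if (weighted) edges$weight <- 1 / (1 + d[cbind(a[keep], b[keep])])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = fm$subject_ids)
  )
  structure(
    list(graph = g, k_nn = k_nn, p = p, symmetrize = symmetrize,
         weighted = weighted, subject_ids = fm$subject_ids),
    class = "transdx_graph"
  )
}

# Dense all-pairs Minkowski distance. Computed by pairwise summation
# (stats::dist) rather than the faster Gram-matrix identity: the identity's
# rounding error breaks exact distance ties inconsistently, which would
# make the documented tie rule depend on floating-point noise.
minkowski_matrix <- function(x, p) {
  method <- if (p == 2) "euclidean" else "minkowski"
  as.matrix(dist(x, method = method, p = p))
}

#' Wrap an existing igraph object as a similarity graph
#'
#' Lets externally constructed graphs (e.g. hand-built toy topologies) feed
#' the Louvain and recommender stages.
#'
#' @param g An undirected igraph with named vertices.
#' @param k_nn,p Build parameters to record (metadata only).
#' @return A `transdx_graph`.
#' @export
as_similarity_graph <- function(g, k_nn = NA_integer_, p = NA_real_) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  structure(
    list(graph = g, k_nn = k_nn, p = p, symmetrize = "union",
         weighted = "weight" %in% igraph::edge_attr_names(g),
         subject_ids = igraph::V(g)$name),
    class = "transdx_graph"
  )
}

#' @export
print.transdx_graph <- function(x, ...) {
  cat("<transdx_graph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (k_nn=", x$k_nn, ", p=", x$p, ", ",
      x$symmetrize, if (x$weighted) ", weighted", ")\n", sep = "")
  invisible(x)
}

#' Edge list of a similarity graph
#'
#' @param x A `transdx_graph`.
#' @param ... Unused.
#' @return Tibble (node_a, node_b) and weight when present.
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_graph <- function(x, ...) {
  el <- igraph::as_data_frame(x$graph, what = "edges")
  out <- tibble::tibble(node_a = el$from, node_b = el$to)
  if (x$weighted && !is.null(el$weight)) out$weight <- el$weight
  out
}

#' Write a similarity graph as an edge-list TSV
#'
#' @param x A `transdx_graph`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graph_edges <- function(x, path) {
  write_table_auto(tidy(x), path)
}
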