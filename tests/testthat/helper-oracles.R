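# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain loops over explicit definitions.

# All-pairs Minkowski distance by explicit summation.
oracle_minkowski <- function(x, p) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(x[i, ] - x[j, ])^p)^(1 / p)
    }
  }
  d
}

# kNN union graph as a sorted character edge set "i-j" (i < j, row indices);
# ties at the k-th rank broken toward the smaller row index. Tie detection
# follows the documented rule: distances are compared at 10 significant
# digits so that mathematically equal distances tie regardless of the
# floating-point summation path.
oracle_knn_edges <- function(x, k_nn, p = 2) {
  d <- signif(oracle_minkowski(x, p), 10)
  n <- nrow(x)
  edges <- character(0)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], others)]
    for (j in ord[seq_len(k_nn)]) {
      edges <- c(edges, paste(min(i, j), max(i, j), sep = "-"))
    }
  }
  sort(unique(edges))
}

# Edge set of a transdx_graph in the same "i-j" row-index format.
graph_edge_set <- function(g, subject_ids) {
  el <- tidy(g)
  a <- match(el$node_a, subject_ids)
  b <- match(el$node_b, subject_ids)
  sort(paste(pmin(a, b), pmax(a, b), sep = "-"))
}

# Standard Newman modularity from an edge list and a membership vector.
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]),
                      levels = seq_along(membership)))
  q <- 0
  for (c in unique(membership)) {
    nodes <- which(membership == c)
    e_c <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Mean silhouette by the textbook per-point formula; singleton-cluster
# points and 0/0 cases score 0.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { widths[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, 0))
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(widths)
}

# Brute-force network recommender: BFS by repeated neighbour expansion
# (no igraph distance call), whole-ring inclusion, competition ranking.
oracle_network_recommend <- function(adj, labeled_sets, subject,
                                     min_labeled, rank_threshold, classes) {
  visited <- subject
  frontier <- subject
  hood <- character(0)
  labeled_in <- character(0)
  rings <- 0L
  quota_unmet <- FALSE
  repeat {
    nxt <- setdiff(unique(unlist(adj[frontier])), visited)
    if (!length(nxt)) { quota_unmet <- length(labeled_in) < min_labeled; break }
    rings <- rings + 1L
    visited <- c(visited, nxt)
    hood <- c(hood, nxt)
    labeled_in <- c(labeled_in, intersect(nxt, names(labeled_sets)))
    frontier <- nxt
    if (length(labeled_in) >= min_labeled) break
  }
  counts <- vapply(classes, function(cl) {
    sum(vapply(labeled_sets[labeled_in], function(s) cl %in% s, TRUE))
  }, 0)
  rk <- as.integer(rank(-counts, ties.method = "min"))
  list(
    counts = counts,
    rank = rk,
    recommended = sort(classes[counts > 0 & rk <= rank_threshold]),
    rings = rings,
    neighborhood_total = length(hood),
    neighborhood_labeled = length(labeled_in),
    quota_unmet = quota_unmet
  )
}

# adjacency list (named) from a transdx_graph
graph_adj_list <- function(g) {
  al <- igraph::as_adj_list(g$graph)
  lapply(al, function(v) igraph::V(g$graph)$name[as.integer(v)])
}
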