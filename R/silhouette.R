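# Silhouette quality of a partition in feature space.
#
# The silhouette of a point is (b - a) / max(a, b) where a is its mean
# distance to its own cluster and b the smallest mean distance to another
# cluster. Degenerate-case conventions: members of singleton clusters score
# 0 (cluster's convention), non-finite widths (all-zero distances) score 0,
# and a partition with fewer than two clusters scores 0 overall.

#' Mean silhouette of a partition
#'
#' All-pairs distances make this O(n^2); above `sample_n` subjects the score
#' is computed on a seeded uniform subsample (reported via a message).
#'
#' @param fm A `transdx_features`.
#' @param labels Integer cluster label per subject (any coding).
#' @param sample_n Subsample cap, default 10000.
#' @param seed Seed for the subsample draw.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(fm, labels, sample_n = 10000, seed = 1) {
  x <- fm$values
  stopifnot(nrow(x) == length(labels))
  idx <- silhouette_subsample(nrow(x), sample_n, seed)
  mean_silhouette(dist(x[idx, , drop = FALSE]), labels[idx])
}

silhouette_subsample <- function(n, sample_n, seed) {
  if (n <= sample_n) return(seq_len(n))
  inform(paste0("silhouette computed on a subsample of ", sample_n,
                " of ", n, " subjects"))
  with_seed(seed, sort(sample.int(n, sample_n)))
}

# Core on a precomputed stats::dist object (reused across sweep entries).
mean_silhouette <- function(d, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) return(0)
  sil <- cluster::silhouette(labels, dist = d)
  w <- sil[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}
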