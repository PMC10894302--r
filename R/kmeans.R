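# k-means clustering with silhouette-based model-size selection.

#' Fit k-means on a standardized feature matrix
#'
#' Lloyd iterations under Euclidean distance with `nstart` random restarts
#' (best total within-cluster inertia kept); deterministic given `seed`.
#' Labels are relabeled contiguously from 0 by descending cluster size.
#'
#' @param fm A standardized `transdx_features`.
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @param iter.max Iteration cap per restart.
#' @param sample_n Silhouette subsample cap (see [silhouette_score()]).
#' @return A `transdx_clusters` with silhouette and inertia recorded.
#' @export
fit_kmeans <- function(fm, k, seed = 1, nstart = 10, iter.max = 100,
                       sample_n = 10000) {
  stopifnot(inherits(fm, "transdx_features"))
  if (!fm$standardized) abort("fit_kmeans requires a standardized feature matrix")
  n <- nrow(fm$values)
  k <- stopifnot_scalar_int(k, "k", lower = 2)
  if (k >= n) abort(paste0("k (", k, ") must be < number of subjects (", n, ")"))

  fit <- fit_kmeans_core(fm, k, seed, nstart, iter.max)
  sil <- silhouette_score(fm, fit$labels, sample_n = sample_n, seed = seed)
  new_clusters(
    method = "kmeans",
    subject_ids = fm$subject_ids,
    labels = fit$labels,
    params = list(k = k, nstart = nstart, iter.max = iter.max),
    quality = list(silhouette = sil, inertia = fit$inertia),
    seed = seed
  )
}

#' Select k by mean silhouette over a grid
#'
#' Fits k-means for every k in `k_grid` and returns the fit with the
#' highest mean silhouette; ties (within 1e-12) break toward smaller k. The
#' full sweep table is returned for audit. All silhouettes are computed on
#' one shared (sub)sample and distance matrix so values are comparable
#' across k.
#'
#' @inheritParams fit_kmeans
#' @param k_grid Integer vector within `[2, n - 1]`.
#' @return List with `best_k`, `sweep` (tibble k, silhouette, inertia) and
#'   `assignment` (the refitted best `transdx_clusters`).
#' @export
select_k_by_silhouette <- function(fm, k_grid, seed = 1, nstart = 10,
                                   sample_n = 10000) {
  n <- nrow(fm$values)
  k_grid <- sort(unique(vapply(k_grid, stopifnot_scalar_int, 1L,
                               name = "k_grid", lower = 2)))
  if (any(k_grid >= n)) abort("k_grid values must be < number of subjects")

  idx <- silhouette_subsample(n, sample_n, seed)
  d <- dist(fm$values[idx, , drop = FALSE])
  fits <- vector("list", length(k_grid))
  sweep_tbl <- purrr::map_dfr(seq_along(k_grid), function(i) {
    fit <- fit_kmeans_nosil(fm, k_grid[i], seed = seed, nstart = nstart)
    fit$quality$silhouette <- mean_silhouette(d, fit$assignments$cluster[idx])
    fits[[i]] <<- fit
    tibble::tibble(k = k_grid[i], silhouette = fit$quality$silhouette,
                   inertia = fit$quality$inertia)
  })
  best_i <- which(sweep_tbl$silhouette >= max(sweep_tbl$silhouette) - 1e-12)[1]
  list(
    best_k = k_grid[best_i],
    sweep = sweep_tbl,
    assignment = fits[[best_i]]
  )
}

# fit without the silhouette pass (the sweep computes it on a shared dist)
fit_kmeans_nosil <- function(fm, k, seed, nstart) {
  fit <- fit_kmeans_core(fm, k, seed, nstart)
  new_clusters(
    method = "kmeans",
    subject_ids = fm$subject_ids,
    labels = fit$labels,
    params = list(k = k, nstart = nstart),
    quality = list(silhouette = NA_real_, inertia = fit$inertia),
    seed = seed
  )
}

fit_kmeans_core <- function(fm, k, seed, nstart, iter.max = 100) {
  n <- nrow(fm$values)
  fit <- with_seed(seed, tryCatch(
    suppressWarnings(
      kmeans(fm$values, centers = k, nstart = nstart, iter.max = iter.max,
             algorithm = "Lloyd")
    ),
    error = function(e) NULL
  ))
  if (is.null(fit)) {
    list(labels = relabel_by_size(rep_len(seq_len(k), n)), inertia = 0)
  } else {
    list(labels = relabel_by_size(fit$cluster), inertia = fit$tot.withinss)
  }
}
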