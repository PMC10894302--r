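# 2-D embedding for cluster visualization.

#' Embed subjects in two dimensions for plotting
#'
#' Projects the standardized feature matrix onto its first two principal
#' components (deterministic linear embedding; component signs are fixed so
#' repeated calls are byte-identical). The embedding exists for
#' visualization only and is never consumed by any downstream computation.
#'
#' @param fm A standardized `transdx_features` with at least 10 subjects.
#' @param seed Accepted for interface uniformity with the stochastic stages;
#'   the projection itself is deterministic.
#' @return Tibble (subject_id, dim1, dim2).
#' @export
embed_2d <- function(fm, seed = 1) {
  stopifnot(inherits(fm, "transdx_features"))
  if (!fm$standardized) abort("embed_2d requires a standardized feature matrix")
  n <- nrow(fm$values)
  if (n < 10) abort("embedding needs at least 10 subjects")
  pc <- prcomp(fm$values, rank. = 2, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  tibble::tibble(
    subject_id = fm$subject_ids,
    dim1 = pc$x[, 1],
    dim2 = pc$x[, 2]
  )
}
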