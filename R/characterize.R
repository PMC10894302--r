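# Cluster characterization: diagnosis flows, penalized-regression feature
# importance, and category index scores.

#' Diagnosis composition of clusters (Sankey flow table)
#'
#' Counts every diagnosis within every cluster, with a `"none"` pseudo-label
#' for subjects holding an empty diagnosis set, and emits the full
#' source-stratum x target-cluster grid (zero flows included) ready for
#' Sankey/alluvial rendering. Passing a second cluster assignment instead of
#' diagnosis labels yields the cluster x cluster overlap table of two
#' methods (e.g. k-means vs Louvain).
#'
#' @param assignment A `transdx_clusters`.
#' @param labels A `transdx_diagnoses`, or a second `transdx_clusters`.
#' @return Tibble (source, target, n); `target` is the cluster id of
#'   `assignment`.
#' @export
diagnosis_composition <- function(assignment, labels) {
  stopifnot(inherits(assignment, "transdx_clusters"))
  asg <- assignment$assignments
  if (inherits(labels, "transdx_clusters")) {
    other <- labels$assignments
    if (!setequal(asg$subject_id, other$subject_id)) {
      abort("assignments cover different subject universes")
    }
    flows <- dplyr::inner_join(
      dplyr::rename(other, source = "cluster"),
      dplyr::rename(asg, target = "cluster"),
      by = "subject_id"
    ) |>
      dplyr::count(.data$source, .data$target)
    return(tidyr::complete(
      flows,
      source = sort(unique(other$cluster)),
      target = sort(unique(asg$cluster)),
      fill = list(n = 0L)
    ))
  }
  stopifnot(inherits(labels, "transdx_diagnoses"))
  if (!setequal(asg$subject_id, labels$subject_id)) {
    abort("assignment and labels cover different subject universes")
  }
  labels <- labels[match(asg$subject_id, labels$subject_id), ]
  strata <- lapply(labels$diagnoses, function(d) if (length(d)) d else "none")
  flows <- tibble::tibble(
    source = unlist(strata),
    target = rep(asg$cluster, lengths(strata))
  ) |>
    dplyr::count(.data$source, .data$target)
  tidyr::complete(
    flows,
    source = sort(unique(unlist(strata))),
    target = sort(unique(asg$cluster)),
    fill = list(n = 0L)
  )
}

#' Per-cluster feature importance by L1-penalized logistic regression
#'
#' For every cluster, fits a lasso-penalized logistic regression of cluster
#' membership (member vs non-member, one-vs-rest) on all standardized
#' features and reports the features whose coefficient exceeds
#' `beta_threshold` (default 0.2), sorted by decreasing coefficient. Because
#' features are standardized, coefficients are on a comparable scale across
#' items.
#'
#' @param fm A standardized `transdx_features`.
#' @param assignment A `transdx_clusters` with at least 2 clusters.
#' @param beta_threshold Coefficient threshold (default 0.2), applied to the
#'   signed coefficient unless `absolute = TRUE`.
#' @param penalty Fixed lasso penalty lambda; `NULL` (default) selects it
#'   per cluster by 3-fold cross-validated deviance.
#' @param seed Integer seed (cross-validation folds).
#' @param absolute Threshold `|beta|` instead of signed beta.
#' @param min_members Clusters smaller than this are skipped with a warning
#'   (default 10).
#' @return Tibble (cluster, feature, beta), descending beta within cluster;
#'   the per-cluster penalty actually used is attached as attribute
#'   `"penalty"`.
#' @export
cluster_feature_importance <- function(fm, assignment, beta_threshold = 0.2,
                                       penalty = NULL, seed = 1,
                                       absolute = FALSE, min_members = 10) {
  stopifnot(inherits(fm, "transdx_features"),
            inherits(assignment, "transdx_clusters"))
  if (!fm$standardized) {
    abort("cluster_feature_importance requires standardized features")
  }
  asg <- assignment$assignments
  stopifnot(identical(asg$subject_id, fm$subject_ids))
  clusters <- sort(unique(asg$cluster))
  if (length(clusters) < 2) abort("need at least 2 clusters")

  x <- fm$values
  out <- list()
  lambdas <- numeric(0)
  for (cl in clusters) {
    y <- as.numeric(asg$cluster == cl)
    if (sum(y) < min_members) {
      warn(paste0("cluster ", cl, " has fewer than ", min_members,
                  " members; skipped"))
      next
    }
    if (sum(1 - y) < min_members) {
      warn(paste0("cluster ", cl, " leaves fewer than ", min_members,
                  " non-members; skipped"))
      next
    }
    lambda <- penalty
    if (is.null(lambda)) {
      cvfit <- with_seed(seed, glmnet::cv.glmnet(
        x, y, family = "binomial", alpha = 1, nfolds = 3,
        standardize = FALSE))
      lambda <- cvfit$lambda.min
      beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
    } else {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                            lambda = lambda, standardize = FALSE)
      beta <- as.matrix(stats::coef(fit))[-1, 1]
    }
    lambdas[as.character(cl)] <- lambda
    keep <- if (absolute) abs(beta) > beta_threshold else beta > beta_threshold
    if (any(keep)) {
      out[[as.character(cl)]] <- tibble::tibble(
        cluster = cl,
        feature = names(beta)[keep],
        beta = unname(beta[keep])
      ) |> dplyr::arrange(dplyr::desc(.data$beta))
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(cluster = integer(), feature = character(),
                   beta = numeric())
  attr(res, "penalty") <- tibble::tibble(
    cluster = as.integer(names(lambdas)), lambda = unname(lambdas))
  attr(res, "beta_threshold") <- beta_threshold
  res
}

#' Category index scores per subject and per cluster
#'
#' Every item is min-max scaled to `[0, 1]` over the full cohort (so scores
#' are comparable across clusters), numeric codes taken at face value and
#' non-numeric codes by their position in the item's ordered value list;
#' each subject's category score is the mean of its scaled items in that
#' category. Items with zero range scale to 0 with a warning.
#'
#' @param cohort A `transdx_cohort`.
#' @param assignment Optional `transdx_clusters` for per-cluster summaries.
#' @return A `transdx_category_scores`: `subject_scores` tibble
#'   (subject_id, category, score) and, with an assignment,
#'   `cluster_summary` (cluster, category, mean, q25, median, q75, n).
#' @export
category_index_scores <- function(cohort, assignment = NULL) {
  stopifnot(inherits(cohort, "transdx_cohort"))
  items <- cohort$items
  resp <- cohort$responses

  scaled <- matrix(NA_real_, nrow(resp), nrow(items),
                   dimnames = list(resp$subject_id, items$item_id))
  flat <- character(0)
  for (i in seq_len(nrow(items))) {
    v <- resp[[items$item_id[i]]]
    v[v %in% items$missing_codes[[i]]] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      num <- as.numeric(match(v, items$allowed_values[[i]]) - 1L)
    }
    rng <- range(num, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      flat <- c(flat, items$item_id[i])
      scaled[, i] <- ifelse(is.na(num), NA_real_, 0)
    } else {
      scaled[, i] <- (num - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(flat)) {
    warn(paste0(length(flat), " zero-range item(s) scaled to 0: ",
                paste(head(flat, 5), collapse = ", ")))
  }

  subject_scores <- purrr::map_dfr(
    sort(unique(items$category)),
    function(cat) {
      cols <- which(items$category == cat)
      tibble::tibble(
        subject_id = resp$subject_id,
        category = cat,
        score = unname(rowMeans(scaled[, cols, drop = FALSE], na.rm = TRUE))
      )
    }
  )

  cluster_summary <- NULL
  if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "transdx_clusters"))
    cluster_summary <- subject_scores |>
      dplyr::inner_join(assignment$assignments, by = "subject_id") |>
      dplyr::group_by(.data$cluster, .data$category) |>
      dplyr::summarise(
        mean = mean(.data$score, na.rm = TRUE),
        q25 = quantile(.data$score, 0.25, na.rm = TRUE, names = FALSE),
        median = quantile(.data$score, 0.50, na.rm = TRUE, names = FALSE),
        q75 = quantile(.data$score, 0.75, na.rm = TRUE, names = FALSE),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  structure(
    list(subject_scores = subject_scores, cluster_summary = cluster_summary),
    class = "transdx_category_scores"
  )
}

#' @export
print.transdx_category_scores <- function(x, ...) {
  cat("<transdx_category_scores> ",
      length(unique(x$subject_scores$subject_id)), " subjects x ",
      length(unique(x$subject_scores$category)), " categories\n", sep = "")
  if (!is.null(x$cluster_summary)) print(x$cluster_summary)
  invisible(x)
}

#' Per-subject category scores
#'
#' @param x A `transdx_category_scores`.
#' @param ... Unused.
#' @return The subject-level score tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_category_scores <- function(x, ...) x$subject_scores
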