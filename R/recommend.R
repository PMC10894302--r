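# Drug-class recommendation engines.
#
# Two engines share the class vocabulary and ranking semantics:
# (1) cluster-based — every member of a cluster receives the classes with
#     the highest within-cluster prescription probability;
# (2) network-based — a subject's neighbourhood on the similarity graph is
#     grown breadth-first, whole ring by whole ring, until it holds at
#     least `min_labeled` prescription-labeled neighbours, and classes are
#     ranked by their prescription count inside that neighbourhood.
# Ranking is competition ranking (ties share a rank); classes with rank at
# or below `rank_threshold` are recommended; zero-count/zero-probability
# classes are never recommended.

#' Per-cluster prescription rate
#'
#' Share of each cluster's members that carry any prescription history.
#'
#' @param assignment A `transdx_clusters`.
#' @param rx A `transdx_prescriptions`; its subjects must all be assigned.
#' @return Tibble (cluster, size, n_labeled, rate); the overall labeled
#'   share is attached as attribute `"overall_rate"`.
#' @export
cluster_prescription_rate <- function(assignment, rx) {
  asg <- check_rx_universe(assignment, rx)
  out <- asg |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_labeled = sum(.data$labeled),
      rate = mean(.data$labeled),
      .groups = "drop"
    )
  attr(out, "overall_rate") <- mean(asg$labeled)
  out
}

#' Per-cluster drug-class prescription probability
#'
#' P(class | cluster) = labeled cluster members holding the class / labeled
#' cluster members. A labeled subject holding several classes contributes to
#' each of them. Clusters without labeled members get missing probabilities
#' and a warning.
#'
#' @inheritParams cluster_prescription_rate
#' @param classes Class vocabulary (default: the prescriptions' vocabulary).
#' @return Tibble (cluster, class, n_labeled, n_class, probability).
#' @export
cluster_class_probability <- function(assignment, rx, classes = NULL) {
  classes <- classes %||% rx$vocabulary
  asg <- check_rx_universe(assignment, rx)
  counts <- rx$classes |>
    dplyr::inner_join(assignment$assignments, by = "subject_id") |>
    dplyr::count(.data$cluster, .data$class, name = "n_class")
  labeled <- asg |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_labeled = sum(.data$labeled), .groups = "drop")
  out <- tidyr::expand_grid(
    cluster = sort(unique(asg$cluster)), class = classes) |>
    dplyr::left_join(labeled, by = "cluster") |>
    dplyr::left_join(counts, by = c("cluster", "class")) |>
    dplyr::mutate(
      n_class = dplyr::coalesce(.data$n_class, 0L),
      probability = ifelse(.data$n_labeled > 0,
                           .data$n_class / .data$n_labeled, NA_real_)
    )
  empty <- unique(out$cluster[out$n_labeled == 0])
  if (length(empty)) {
    warn(paste0("cluster(s) without labeled members, probabilities missing: ",
                paste(empty, collapse = ", ")))
  }
  out
}

check_rx_universe <- function(assignment, rx) {
  stopifnot(inherits(assignment, "transdx_clusters"),
            inherits(rx, "transdx_prescriptions"))
  asg <- assignment$assignments
  stray <- setdiff(rx$subjects, asg$subject_id)
  if (length(stray)) {
    abort(paste0(length(stray),
                 " prescription subject(s) missing from the assignment"))
  }
  dplyr::mutate(asg, labeled = .data$subject_id %in% rx$subjects)
}

#' Cluster-based drug-class recommendation
#'
#' Ranks classes by their prescription probability in the subject's cluster
#' (competition ranking, descending) and recommends those with rank at or
#' below `rank_threshold`; ties are included, so a tie at the cutoff can
#' recommend more classes than the threshold. Identical for all members of
#' a cluster.
#'
#' @param assignment A `transdx_clusters`.
#' @param probability_table Output of [cluster_class_probability()].
#' @param subjects Subjects to recommend for; default all assigned.
#' @param rank_threshold Maximum recommended rank (default 3).
#' @return Tibble, one row per subject x class: probability, rank,
#'   recommended flag.
#' @export
cluster_based_recommend <- function(assignment, probability_table,
                                    subjects = NULL, rank_threshold = 3) {
  stopifnot(inherits(assignment, "transdx_clusters"))
  rank_threshold <- stopifnot_scalar_int(rank_threshold, "rank_threshold", 1)
  asg <- assignment$assignments
  subjects <- subjects %||% asg$subject_id
  missing_subj <- setdiff(subjects, asg$subject_id)
  if (length(missing_subj)) {
    abort(paste0("subject(s) not in the assignment: ",
                 paste(head(missing_subj, 5), collapse = ", ")))
  }
  ranked <- probability_table |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(rank = competition_rank(.data$probability)) |>
    dplyr::ungroup() |>
    dplyr::mutate(recommended = !is.na(.data$probability) &
                    .data$probability > 0 & .data$rank <= rank_threshold)
  undefined <- unique(probability_table$cluster[
    is.na(probability_table$probability)])
  need <- unique(asg$cluster[asg$subject_id %in% subjects])
  bad <- intersect(need, undefined)
  if (length(bad)) {
    abort(paste0("cluster(s) ", paste(bad, collapse = ", "),
                 " have no labeled members; use network_based_recommend()",
                 " for their subjects"))
  }
  tibble::tibble(subject_id = subjects) |>
    dplyr::inner_join(asg, by = "subject_id") |>
    dplyr::inner_join(ranked, by = "cluster",
                      relationship = "many-to-many") |>
    dplyr::select("subject_id", "cluster", "class", "probability",
                  "rank", "recommended") |>
    dplyr::arrange(.data$subject_id, .data$rank, .data$class)
}

#' Network-based adaptive-neighbourhood recommendation
#'
#' For each target subject, the neighbourhood on the similarity graph grows
#' breadth-first: ring 1 holds the direct neighbours, ring r the nodes at
#' graph distance r. Whole rings are always included — expansion stops after
#' the first complete ring at which the cumulative number of
#' prescription-labeled neighbours reaches `min_labeled` (default 20). Class
#' prescription counts are then tallied over the labeled neighbourhood
#' members (the target itself is always excluded, so evaluation on labeled
#' subjects is leakage-free), competition-ranked by count, and classes with
#' rank at or below `rank_threshold` and a nonzero count are recommended.
#'
#' If the subject's graph component is exhausted before the quota is met,
#' the recommendation is computed on all available labeled members and
#' flagged `quota_unmet`; a component with no labeled members at all is an
#' error.
#'
#' @param g A `transdx_graph`.
#' @param rx A `transdx_prescriptions`.
#' @param subjects Subjects to recommend for; default every labeled subject
#'   present in the graph (the evaluation population).
#' @param min_labeled Labeled-neighbour quota (default 20).
#' @param rank_threshold Maximum recommended rank (default 3).
#' @param classes Class vocabulary (default: the prescriptions' vocabulary).
#' @return Tibble, one row per subject x class: count, frequency (count /
#'   labeled neighbourhood size), rank, recommended, plus the per-subject
#'   provenance columns rings_expanded, neighborhood_total,
#'   neighborhood_labeled and quota_unmet.
#' @export
network_based_recommend <- function(g, rx, subjects = NULL, min_labeled = 20,
                                    rank_threshold = 3, classes = NULL) {
  stopifnot(inherits(g, "transdx_graph"),
            inherits(rx, "transdx_prescriptions"))
  min_labeled <- stopifnot_scalar_int(min_labeled, "min_labeled", 1)
  rank_threshold <- stopifnot_scalar_int(rank_threshold, "rank_threshold", 1)
  classes <- classes %||% rx$vocabulary
  nodes <- g$subject_ids
  labeled_nodes <- intersect(nodes, rx$subjects)
  if (!length(labeled_nodes)) abort("no labeled subjects in the graph")
  subjects <- subjects %||% labeled_nodes
  missing_subj <- setdiff(subjects, nodes)
  if (length(missing_subj)) {
    abort(paste0("subject(s) not in the graph: ",
                 paste(head(missing_subj, 5), collapse = ", ")))
  }
  sets <- prescription_sets(rx)
  is_labeled <- setNames(nodes %in% rx$subjects, nodes)

  purrr::map_dfr(subjects, function(s) {
    dvec <- igraph::distances(g$graph, v = s, weights = NA)[1, ]
    dvec <- dvec[names(dvec) != s]
    finite <- dvec[is.finite(dvec)]
    if (!any(is_labeled[names(finite)])) {
      abort(paste0("subject ", s,
                   "'s graph component has no labeled members"))
    }
    rings <- sort(unique(finite))
    cum_labeled <- cumsum(vapply(
      rings, function(r) sum(is_labeled[names(finite)[finite == r]]), 0))
    reached <- which(cum_labeled >= min_labeled)
    quota_unmet <- !length(reached)
    r_star <- if (quota_unmet) max(rings) else rings[reached[1]]
    hood <- names(finite)[finite <= r_star]
    lab_hood <- hood[is_labeled[hood]]
    counts <- vapply(classes, function(cl) {
      sum(vapply(sets[lab_hood], function(x) cl %in% x, TRUE))
    }, 0)
    rk <- competition_rank(counts)
    tibble::tibble(
      subject_id = s,
      class = classes,
      count = as.integer(counts),
      frequency = counts / length(lab_hood),
      rank = rk,
      recommended = counts > 0 & rk <= rank_threshold,
      rings_expanded = as.integer(r_star),
      neighborhood_total = length(hood),
      neighborhood_labeled = length(lab_hood),
      quota_unmet = quota_unmet
    ) |> dplyr::arrange(.data$rank, .data$class)
  })
}

#' Evaluate recommendations against observed prescriptions
#'
#' Compares each subject's recommended class set with the classes actually
#' prescribed: a hit is a non-empty intersection, an exact match is set
#' equality. Also reports the distribution of recommendation-list sizes
#' (driven by ties) and the per-class recommendation frequency, overall and
#' per cluster when an assignment is supplied.
#'
#' @param recs Recommendation tibble from either engine.
#' @param rx A `transdx_prescriptions`; every evaluated subject must be
#'   labeled.
#' @param assignment Optional `transdx_clusters` for per-cluster frequency.
#' @return A `transdx_rec_eval` with `per_subject`, `size_distribution`,
#'   `class_frequency` tibbles and `hit_rate` / `exact_rate`.
#' @export
evaluate_recommendations <- function(recs, rx, assignment = NULL) {
  stopifnot(inherits(rx, "transdx_prescriptions"))
  subjects <- unique(recs$subject_id)
  unlabeled <- setdiff(subjects, rx$subjects)
  if (length(unlabeled)) {
    abort(paste0(length(unlabeled), " evaluated subject(s) have no",
                 " prescription record"))
  }
  sets <- prescription_sets(rx)
  rec_sets <- recs |>
    dplyr::filter(.data$recommended) |>
    (\(d) split(d$class, d$subject_id))()
  per_subject <- tibble::tibble(
    subject_id = subjects,
    n_recommended = unname(lengths(rec_sets[subjects])),
    hit = vapply(subjects, function(s) {
      length(intersect(rec_sets[[s]], sets[[s]])) > 0
    }, TRUE),
    exact = vapply(subjects, function(s) {
      setequal(rec_sets[[s]], sets[[s]])
    }, TRUE)
  )
  size_distribution <- per_subject |>
    dplyr::count(.data$n_recommended, name = "n_subjects") |>
    dplyr::mutate(share = .data$n_subjects / sum(.data$n_subjects))
  class_frequency <- recs |>
    dplyr::filter(.data$recommended) |>
    dplyr::count(.data$class, name = "n_recommended") |>
    dplyr::mutate(share = .data$n_recommended / length(subjects))
  cluster_frequency <- NULL
  if (!is.null(assignment)) {
    cluster_frequency <- recs |>
      dplyr::filter(.data$recommended) |>
      dplyr::select("subject_id", "class") |>
      dplyr::inner_join(assignment$assignments, by = "subject_id") |>
      dplyr::count(.data$cluster, .data$class, name = "n_recommended")
  }
  structure(
    list(
      per_subject = per_subject,
      size_distribution = size_distribution,
      class_frequency = class_frequency,
      cluster_frequency = cluster_frequency,
      hit_rate = mean(per_subject$hit),
      exact_rate = mean(per_subject$exact)
    ),
    class = "transdx_rec_eval"
  )
}

#' @export
print.transdx_rec_eval <- function(x, ...) {
  cat("<transdx_rec_eval> ", nrow(x$per_subject), " subjects, hit rate ",
      sprintf("%.2f%%", 100 * x$hit_rate), ", exact ",
      sprintf("%.2f%%", 100 * x$exact_rate), "\n", sep = "")
  print(x$size_distribution)
  invisible(x)
}

#' Per-subject evaluation flags
#'
#' @param x A `transdx_rec_eval`.
#' @param ... Unused.
#' @return The per-subject tibble (n_recommended, hit, exact).
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_rec_eval <- function(x, ...) x$per_subject

#' One-row evaluation summary
#'
#' @param x A `transdx_rec_eval`.
#' @param ... Unused.
#' @return Tibble with subject count, hit and exact-match rates.
#' @export
#' @exportS3Method generics::glance
glance.transdx_rec_eval <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$per_subject),
    hit_rate = x$hit_rate,
    exact_rate = x$exact_rate,
    mean_n_recommended = mean(x$per_subject$n_recommended)
  )
}
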