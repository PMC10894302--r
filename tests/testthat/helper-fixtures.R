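# In-code fixtures: tiny cohorts and graphs built programmatically.

toy_items <- function() {
  item_definitions(
    item_id = c("A01", "B01"),
    category = c("A", "B"),
    value_kind = c("binary", "ordinal"),
    allowed_values = list(c("0", "1"), c("0", "1", "2")),
    missing_codes = list("-9", "-9")
  )
}

toy_cohort <- function() {
  cohort(
    tibble::tibble(
      subject_id = c("s1", "s2", "s3"),
      age = c(30, 40, 50),
      sex = c("F", "M", "F"),
      A01 = c("0", "1", "1"),
      B01 = c("0", "2", "1")
    ),
    toy_items()
  )
}

# feature object straight from a numeric matrix (bypasses encoding)
features_from_matrix <- function(m, standardized = FALSE, ids = NULL) {
  ids <- ids %||% sprintf("s%03d", seq_len(nrow(m)))
  rownames(m) <- ids
  colnames(m) <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
  transdx:::new_features(
    m,
    tibble::tibble(feature = colnames(m), item_id = NA_character_,
                   role = "numeric"),
    standardized = standardized
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two disjoint 5-cliques as a similarity graph, nodes n1..n10
two_cliques_graph <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("n", 1:10)
  as_similarity_graph(g)
}

# Erdos-Renyi similarity graph with named nodes (seeded by caller)
random_graph <- function(n, p_edge) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  as_similarity_graph(g)
}

# random prescriptions over a subset of the given subjects
random_prescriptions <- function(subjects, frac,
                                 classes = default_drug_classes()) {
  labeled <- subjects[stats::runif(length(subjects)) < frac]
  if (!length(labeled)) labeled <- subjects[1]
  pairs <- lapply(labeled, function(s) {
    k <- sample(1:3, 1)
    tibble::tibble(subject_id = s,
                   class = sample(classes, k))
  })
  tab <- dplyr::bind_rows(pairs)
  prescriptions(tab$subject_id, tab$class, classes = classes)
}
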