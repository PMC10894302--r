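# Cluster- and network-based recommendation engines and their evaluation.

make_assignment <- function(ids, labels) {
  transdx:::new_clusters("kmeans", ids, labels,
                         params = list(k = length(unique(labels))),
                         quality = list(), seed = 1)
}

rx_from_sets <- function(sets) {
  tab <- dplyr::bind_rows(lapply(names(sets), function(s) {
    tibble::tibble(subject_id = s, class = sets[[s]])
  }))
  prescriptions(tab$subject_id, tab$class)
}

test_that("prescription rates are per-cluster label shares", {
  ids <- sprintf("s%02d", 1:20)
  asg <- make_assignment(ids, rep(c(0, 1), each = 10))
  rx <- rx_from_sets(setNames(rep(list("AD"), 3), ids[1:3]))
  rates <- cluster_prescription_rate(asg, rx)
  expect_equal(rates$rate[rates$cluster == 0], 0.3)
  expect_equal(rates$rate[rates$cluster == 1], 0)
  expect_equal(attr(rates, "overall_rate"), 0.15)
  # all labeled -> rate 1 everywhere
  rx_all <- rx_from_sets(setNames(rep(list("AD"), 20), ids))
  expect_true(all(cluster_prescription_rate(asg, rx_all)$rate == 1))
})

test_that("class probabilities count multi-class members per class", {
  ids <- sprintf("s%02d", 1:6)
  asg <- make_assignment(ids, c(0, 0, 0, 1, 1, 1))
  rx <- rx_from_sets(list(
    s01 = "AD", s02 = "AD", s03 = c("AD", "SH"), s04 = "MS"))
  probs <- cluster_class_probability(asg, rx)
  p <- function(cl, cls) probs$probability[probs$cluster == cl &
                                             probs$class == cls]
  expect_equal(p(0, "AD"), 1)
  expect_equal(p(0, "SH"), 1 / 3)
  expect_equal(p(0, "AP"), 0)
  expect_equal(p(1, "MS"), 1)
  expect_equal(p(1, "AD"), 0)
})

test_that("zero-labeled clusters yield missing probabilities and a warning", {
  ids <- sprintf("s%02d", 1:6)
  asg <- make_assignment(ids, c(0, 0, 0, 1, 1, 1))
  rx <- rx_from_sets(list(s01 = "AD"))
  expect_warning(probs <- cluster_class_probability(asg, rx), "cluster")
  expect_true(all(is.na(probs$probability[probs$cluster == 1])))
  expect_error(cluster_based_recommend(asg, suppressWarnings(
    cluster_class_probability(asg, rx))), "network_based_recommend")
})

test_that("cluster engine ranks by probability with competition ties", {
  ids <- sprintf("s%02d", 1:4)
  asg <- make_assignment(ids, rep(0, 4))
  probs <- tibble::tibble(
    cluster = 0, class = c("AD", "SH", "AP", "MS"),
    n_labeled = 10, n_class = c(8, 2, 0, 0),
    probability = c(0.8, 0.2, 0, 0))
  rec1 <- cluster_based_recommend(asg, probs, rank_threshold = 1)
  expect_equal(rec1$class[rec1$recommended & rec1$subject_id == "s01"], "AD")
  # tie at rank 1 recommends both despite threshold 1
  probs$probability <- c(0.5, 0.5, 0.1, 0)
  probs$n_class <- c(5, 5, 1, 0)
  rec_tie <- cluster_based_recommend(asg, probs, rank_threshold = 1)
  expect_setequal(rec_tie$class[rec_tie$recommended &
                                  rec_tie$subject_id == "s01"],
                  c("AD", "SH"))
  # zero-probability classes are never recommended even under rank 3
  probs$probability <- c(0.9, 0, 0, 0)
  probs$n_class <- c(9, 0, 0, 0)
  rec0 <- cluster_based_recommend(asg, probs, rank_threshold = 3)
  expect_equal(rec0$class[rec0$recommended & rec0$subject_id == "s01"], "AD")
  # identical for all members of the cluster
  expect_equal(dplyr::n_distinct(dplyr::summarise(
    dplyr::group_by(rec_tie, .data$subject_id),
    key = paste(sort(.data$class[.data$recommended]), collapse = ";")
  )$key), 1)
})

test_that("ring expansion stops at the first complete quota-meeting ring", {
  # star-of-rings toy: target t; ring1 = a1..a6 (5 labeled); ring2 = b1..b18
  # (all labeled) -> quota 20 met after ring 2 with 23 labeled
  edges <- list()
  ring1 <- sprintf("a%d", 1:6)
  ring2 <- sprintf("b%d", 1:18)
  el <- rbind(
    cbind("t", ring1),
    cbind(rep(ring1, each = 3), ring2[1:18])
  )
  g <- as_similarity_graph(igraph::graph_from_edgelist(el, directed = FALSE))
  sets <- c(setNames(rep(list("AD"), 5), ring1[1:5]),
            setNames(rep(list("SH"), 18), ring2))
  rx <- rx_from_sets(sets)
  rec <- network_based_recommend(g, rx, subjects = "t", min_labeled = 20)
  expect_equal(unique(rec$rings_expanded), 2L)
  expect_equal(unique(rec$neighborhood_labeled), 23L)
  expect_equal(unique(rec$neighborhood_total), 24L)
  expect_false(unique(rec$quota_unmet))
  expect_equal(rec$count[rec$class == "SH"], 18L)
  expect_equal(rec$count[rec$class == "AD"], 5L)
})

test_that("count ties share a rank and widen the recommended set", {
  g <- as_similarity_graph(igraph::make_full_graph(21))
  ids <- as.character(1:21)
  sets <- c(setNames(rep(list("AD"), 10), ids[2:11]),
            setNames(rep(list("SH"), 10), ids[12:21]))
  rx <- rx_from_sets(sets)
  rec <- network_based_recommend(g, rx, subjects = "1", min_labeled = 20,
                                 rank_threshold = 3)
  recd <- rec[rec$recommended, ]
  expect_setequal(recd$class, c("AD", "SH"))
  expect_equal(unique(recd$rank), 1L)
  # unanimity: only the single held class comes back
  rx_uni <- rx_from_sets(setNames(rep(list("AD"), 20), ids[2:21]))
  rec_uni <- network_based_recommend(g, rx_uni, subjects = "1",
                                     min_labeled = 20)
  expect_equal(rec_uni$class[rec_uni$recommended], "AD")
})

test_that("exhausted components fall back to all labeled members, flagged", {
  g <- two_cliques_graph()  # n1..n5 | n6..n10
  rx <- rx_from_sets(list(n2 = "AD", n3 = c("AD", "MS")))
  rec <- network_based_recommend(g, rx, subjects = "n1", min_labeled = 20)
  expect_true(unique(rec$quota_unmet))
  expect_equal(unique(rec$neighborhood_labeled), 2L)
  expect_setequal(rec$class[rec$recommended], c("AD", "MS"))
  # the other component has no labeled members at all
  expect_error(network_based_recommend(g, rx, subjects = "n6"),
               "no labeled members")
})

test_that("the target's own prescriptions are excluded from its tally", {
  g <- as_similarity_graph(igraph::make_full_graph(5))
  rx <- rx_from_sets(list(`1` = "AP", `2` = "AD", `3` = "AD"))
  rec <- network_based_recommend(g, rx, subjects = "1", min_labeled = 2)
  expect_equal(rec$count[rec$class == "AP"], 0L)
  expect_equal(rec$count[rec$class == "AD"], 2L)
})

test_that("network engine equals the brute-force oracle on random configs", {
  withr::local_seed(77)
  for (rep in 1:20) {
    g <- random_graph(sample(30:120, 1), runif(1, 0.04, 0.12))
    ids <- g$subject_ids
    frac <- runif(1, 0.05, 0.5)
    rx <- random_prescriptions(ids, frac)
    min_labeled <- sample(c(1, 5, 20), 1)
    subj <- sample(ids, 1)
    comp_nodes <- names(which(is.finite(
      igraph::distances(g$graph, v = subj, weights = NA)[1, ])))
    labeled_in_comp <- setdiff(intersect(comp_nodes, rx$subjects), subj)
    adj <- graph_adj_list(g)
    sets <- prescription_sets(rx)
    if (!length(labeled_in_comp)) {
      expect_error(network_based_recommend(g, rx, subjects = subj,
                                           min_labeled = min_labeled))
      next
    }
    rec <- network_based_recommend(g, rx, subjects = subj,
                                   min_labeled = min_labeled)
    orc <- oracle_network_recommend(adj, sets[setdiff(names(sets), subj)],
                                    subj, min_labeled, 3,
                                    default_drug_classes())
    expect_equal(setNames(rec$count[match(names(orc$counts), rec$class)],
                          names(orc$counts)),
                 setNames(as.integer(orc$counts), names(orc$counts)))
    expect_setequal(rec$class[rec$recommended], orc$recommended)
    expect_equal(unique(rec$neighborhood_total), orc$neighborhood_total)
    expect_equal(unique(rec$neighborhood_labeled), orc$neighborhood_labeled)
    expect_equal(unique(rec$quota_unmet), orc$quota_unmet)
  }
})

test_that("enlarging the quota never shrinks the neighbourhood", {
  withr::local_seed(78)
  g <- random_graph(120, 0.06)
  rx <- random_prescriptions(g$subject_ids, 0.3)
  subj <- setdiff(g$subject_ids, rx$subjects)[1]
  totals <- vapply(c(1, 5, 10, 20), function(ml) {
    rec <- network_based_recommend(g, rx, subjects = subj, min_labeled = ml)
    unique(rec$neighborhood_total)
  }, 1L)
  expect_true(all(diff(totals) >= 0))
})

test_that("evaluation reports hits, exact matches and size distribution", {
  ids <- sprintf("s%02d", 1:4)
  asg <- make_assignment(ids, rep(0, 4))
  rx <- rx_from_sets(list(s01 = "AD", s02 = "MS", s03 = c("AD", "SH"),
                          s04 = "AD"))
  recs <- tibble::tibble(
    subject_id = rep(ids, each = 4),
    class = rep(default_drug_classes(), 4),
    recommended = c(
      TRUE, FALSE, FALSE, FALSE,    # s01: {AD} vs {AD} hit+exact
      TRUE, FALSE, FALSE, FALSE,    # s02: {AD} vs {MS} miss
      TRUE, FALSE, FALSE, TRUE,     # s03: {AD,SH} vs {AD,SH} hit+exact
      TRUE, FALSE, TRUE, FALSE      # s04: {AD,MS} vs {AD} hit, not exact
    ))
  ev <- evaluate_recommendations(recs, rx, asg)
  expect_equal(ev$hit_rate, 0.75)
  expect_equal(ev$exact_rate, 0.5)
  dist <- ev$size_distribution
  expect_equal(dist$share[dist$n_recommended == 1], 0.5)
  expect_equal(dist$share[dist$n_recommended == 2], 0.5)
  expect_equal(
    ev$class_frequency$share[ev$class_frequency$class == "AD"], 1)
  # unlabeled subjects in the evaluation are an error
  recs_bad <- dplyr::mutate(recs,
                            subject_id = sub("s01", "zz", .data$subject_id))
  expect_error(evaluate_recommendations(recs_bad, rx), "no")
})
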