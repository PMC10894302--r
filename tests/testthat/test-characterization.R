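# Cluster characterization: flows, lasso importance, category scores.

make_assignment <- function(ids, labels) {
  transdx:::new_clusters("kmeans", ids, labels,
                         params = list(k = length(unique(labels))),
                         quality = list(), seed = 1)
}

test_that("diagnosis flows reproduce hand counts and conserve totals", {
  ids <- sprintf("s%d", 1:6)
  asg <- make_assignment(ids, c(0, 0, 0, 1, 1, 1))
  dx <- diagnosis_labels(
    ids,
    list("depression", "depression", character(0),
         character(0), character(0), character(0)),
    source = "score_based")
  flows <- diagnosis_composition(asg, dx)
  get <- function(s, t) flows$n[flows$source == s & flows$target == t]
  expect_equal(get("depression", 0), 2)
  expect_equal(get("none", 0), 1)
  expect_equal(get("depression", 1), 0)
  expect_equal(get("none", 1), 3)
  # conservation: each stratum's flows sum to its total count
  totals <- tapply(flows$n, flows$source, sum)
  expect_equal(unname(totals["depression"]), 2)
  expect_equal(unname(totals["none"]), 4)
})

test_that("single-cluster cohorts yield a single flow of size n", {
  ids <- sprintf("s%d", 1:5)
  asg <- make_assignment(ids, rep(0, 5))
  dx <- diagnosis_labels(ids, rep(list("depression"), 5), "score_based")
  flows <- diagnosis_composition(asg, dx)
  expect_equal(nrow(flows), 1)
  expect_equal(flows$n, 5)
})

test_that("two assignments produce a cluster-overlap table", {
  ids <- sprintf("s%d", 1:6)
  a <- make_assignment(ids, c(0, 0, 0, 1, 1, 1))
  b <- make_assignment(ids, c(0, 0, 1, 1, 1, 1))
  overlap <- diagnosis_composition(a, b)
  expect_equal(overlap$n[overlap$source == 0 & overlap$target == 0], 2)
  expect_equal(overlap$n[overlap$source == 1 & overlap$target == 0], 1)
  expect_equal(sum(overlap$n), 6)
})

test_that("a planted perfectly-discriminative feature dominates its cluster", {
  withr::local_seed(51)
  n <- 500
  labels <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 1] <- as.numeric(labels == 0)  # perfect separator for cluster 0
  colnames(x) <- paste0("f", 1:10)
  fm <- standardize(features_from_matrix(x))
  asg <- make_assignment(fm$subject_ids, labels)
  imp <- cluster_feature_importance(fm, asg, seed = 3)
  top0 <- imp[imp$cluster == 0, ]
  expect_equal(top0$feature[1], "f1")
  expect_gt(top0$beta[1], 0.2)
})

test_that("importance vanishes when membership is independent of features", {
  withr::local_seed(52)
  n <- 300
  x <- matrix(rnorm(n * 8), n, 8)
  labels <- sample(0:1, n, replace = TRUE)
  fm <- standardize(features_from_matrix(x))
  asg <- make_assignment(fm$subject_ids, labels)
  imp <- cluster_feature_importance(fm, asg, seed = 3)
  expect_equal(nrow(imp), 0)
})

test_that("permuting labels destroys the planted recovery", {
  withr::local_seed(53)
  n <- 400
  labels <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 1] <- as.numeric(labels == 0)
  colnames(x) <- paste0("f", 1:6)
  fm <- standardize(features_from_matrix(x))
  hits <- 0
  for (rep in 1:10) {
    perm <- sample(labels)
    imp <- cluster_feature_importance(
      fm, make_assignment(fm$subject_ids, perm), seed = rep)
    if ("f1" %in% imp$feature[imp$cluster == 0]) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("small clusters are skipped with a warning", {
  withr::local_seed(54)
  fm <- standardize(features_from_matrix(matrix(rnorm(200), 40, 5)))
  labels <- c(rep(0, 30), rep(1, 8), rep(2, 2))
  w <- testthat::capture_warnings(
    imp <- cluster_feature_importance(
      fm, make_assignment(fm$subject_ids, labels), seed = 1))
  expect_true(any(grepl("cluster 1 has fewer than", w)))
  expect_true(any(grepl("cluster 2 has fewer than", w)))
  expect_false(any(imp$cluster %in% c(1, 2)))
})

test_that("category scores follow the hand-computed min-max means", {
  items <- item_definitions(
    c("A01", "A02"), c("A", "A"), c("ordinal", "ordinal"),
    list(as.character(0:4), as.character(0:2)),
    missing_codes = list("-9", "-9"))
  ch <- cohort(
    tibble::tibble(
      subject_id = c("s1", "s2", "s3"), age = c(20, 30, 40),
      sex = c("F", "M", "F"),
      A01 = c("0", "2", "4"), A02 = c("0", "1", "2")
    ), items)
  cs <- category_index_scores(ch)
  s <- cs$subject_scores
  # s2: item scaled values (2-0)/4 = 0.5 and (1-0)/2 = 0.5 -> mean 0.5
  expect_equal(s$score[s$subject_id == "s2"], 0.5)
  # cohort max on both items -> 1; min -> 0
  expect_equal(s$score[s$subject_id == "s3"], 1)
  expect_equal(s$score[s$subject_id == "s1"], 0)
})

test_that("scores are invariant to positive affine recoding and lie in [0,1]", {
  withr::local_seed(55)
  raw <- matrix(sample(0:4, 60, replace = TRUE), 20, 3)
  ch1 <- cohort(
    tibble::tibble(subject_id = sprintf("s%02d", 1:20), age = 1:20,
                   sex = rep(c("F", "M"), 10),
                   A01 = as.character(raw[, 1]), A02 = as.character(raw[, 2]),
                   B01 = as.character(raw[, 3])),
    item_definitions(c("A01", "A02", "B01"), c("A", "A", "B"),
                     rep("continuous", 3),
                     lapply(1:3, function(j) as.character(sort(unique(raw[, j]))))))
  aff <- 3 * raw + 7
  ch2 <- cohort(
    tibble::tibble(subject_id = sprintf("s%02d", 1:20), age = 1:20,
                   sex = rep(c("F", "M"), 10),
                   A01 = as.character(aff[, 1]), A02 = as.character(aff[, 2]),
                   B01 = as.character(aff[, 3])),
    item_definitions(c("A01", "A02", "B01"), c("A", "A", "B"),
                     rep("continuous", 3),
                     lapply(1:3, function(j) as.character(sort(unique(aff[, j]))))))
  s1 <- category_index_scores(ch1)$subject_scores
  s2 <- category_index_scores(ch2)$subject_scores
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  expect_true(all(s1$score >= 0 & s1$score <= 1))
})

test_that("zero-range items scale to 0 with a warning", {
  items <- item_definitions(c("A01", "A02"), c("A", "A"),
                            c("binary", "ordinal"),
                            list(c("0", "1"), as.character(0:2)))
  ch <- cohort(tibble::tibble(
    subject_id = c("s1", "s2"), age = c(20, 30), sex = c("F", "M"),
    A01 = c("1", "1"), A02 = c("0", "2")), items)
  expect_warning(cs <- category_index_scores(ch), "zero-range")
  expect_equal(cs$subject_scores$score, c(0, 0.5))
})

test_that("per-cluster summaries aggregate member subjects", {
  items <- toy_items()
  ch <- toy_cohort()
  asg <- make_assignment(c("s1", "s2", "s3"), c(0, 1, 1))
  cs <- category_index_scores(ch, asg)
  expect_s3_class(cs$cluster_summary, "tbl_df")
  expect_setequal(unique(cs$cluster_summary$cluster), c(0, 1))
  b1 <- cs$cluster_summary[cs$cluster_summary$cluster == 1 &
                             cs$cluster_summary$category == "B", ]
  expect_equal(b1$mean, mean(c(1, 0.5)))  # s2 code 2/2, s3 code 1/2
})
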