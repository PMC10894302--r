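# Cohort loading, validation and file round-trips.

test_that("well-formed responses and items round-trip through files", {
  ch <- toy_cohort()
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  ch2 <- load_cohort(file.path(dir, "responses.tsv"),
                     file.path(dir, "items.tsv"))
  expect_equal(nrow(ch2$subjects), 3)
  expect_equal(nrow(ch2$items), 2)
  expect_equal(ch2$responses, ch$responses)
  expect_equal(ch2$subjects$age, ch$subjects$age)
})

test_that("validation rejects unknown codes, duplicate ids, uncovered columns", {
  items <- toy_items()
  base <- tibble::tibble(
    subject_id = c("s1", "s2"), age = c(30, 40), sex = c("F", "M"),
    A01 = c("0", "1"), B01 = c("0", "2")
  )
  bad_code <- base; bad_code$A01[2] <- "9"
  expect_error(cohort(bad_code, items), "A01.*s2|s2.*A01")

  dup <- base; dup$subject_id <- c("s1", "s1")
  expect_error(cohort(dup, items), "s1")

  extra <- base; extra$Z99 <- c("0", "0")
  expect_error(cohort(extra, items), "Z99")

  # missing codes are legal input
  ok <- base; ok$A01[1] <- "-9"
  expect_s3_class(cohort(ok, items), "transdx_cohort")
})

test_that("malformed subject ids are dropped with a message, not an error", {
  items <- toy_items()
  tab <- tibble::tibble(
    subject_id = c("s1", NA, "s3"), age = c(30, 40, 50),
    sex = c("F", "M", "F"), A01 = c("0", "1", "1"), B01 = c("0", "2", "1")
  )
  expect_message(ch <- cohort(tab, items), "1 row")
  expect_equal(ch$subjects$subject_id, c("s1", "s3"))
})

test_that("item metadata invariants are enforced", {
  expect_error(
    item_definitions("i1", "Z", "binary", list(c("0", "1"))),
    "A-H")
  expect_error(
    item_definitions("i1", "A", "binary", list(c("0", "1")),
                     missing_codes = list("1")),
    "overlap")
  expect_error(
    item_definitions(c("i1", "i1"), c("A", "A"), c("binary", "binary"),
                     list(c("0", "1"), c("0", "1"))),
    "duplicate")
})

test_that("encoding expands categoricals and appends demographics", {
  items <- item_definitions(
    item_id = c("C01", "A01"),
    category = c("C", "A"),
    value_kind = c("categorical", "binary"),
    allowed_values = list(c("a", "b", "c"), c("0", "1")),
    missing_codes = list("-9", "-9")
  )
  ch <- cohort(
    tibble::tibble(
      subject_id = c("s1", "s2", "s3"), age = c(20, 30, 40),
      sex = c("F", "M", "M"),
      C01 = c("a", "b", "c"), A01 = c("0", "1", "0")
    ), items)
  fm <- encode_features(ch)
  # 3 indicators + 1 binary + age + sex
  expect_equal(ncol(fm$values), 6)
  expect_setequal(fm$provenance$feature,
                  c("C01=a", "C01=b", "C01=c", "A01", "age", "sex"))
  expect_equal(unname(fm$values[, "C01=b"]), c(0, 1, 0))
  expect_equal(unname(fm$values[, "sex"]), c(0, 1, 1))
})

test_that("missing-value indicators are dropped or kept by flag", {
  items <- item_definitions(
    "C01", "C", "categorical", list(c("a", "b")), missing_codes = list("-9"))
  ch <- cohort(
    tibble::tibble(subject_id = c("s1", "s2"), age = c(20, 30),
                   sex = c("F", "M"), C01 = c("a", "-9")),
    items)
  fm_drop <- encode_features(ch, drop_missing_indicators = TRUE)
  expect_false("C01=-9" %in% fm_drop$provenance$feature)
  # the missing-code subject scores zero on all kept indicators
  expect_equal(unname(fm_drop$values["s2", c("C01=a", "C01=b")]), c(0, 0))
  fm_keep <- encode_features(ch, drop_missing_indicators = FALSE)
  expect_true("C01=-9" %in% fm_keep$provenance$feature)
  expect_equal(unname(fm_keep$values["s2", "C01=-9"]), 1)
})

test_that("constant responses encode fine; all-missing items error", {
  items <- item_definitions(
    c("C01", "A01"), c("C", "A"), c("categorical", "binary"),
    list(c("a", "b"), c("0", "1")), missing_codes = list("-9", "-9"))
  ch <- cohort(
    tibble::tibble(subject_id = c("s1", "s2"), age = c(20, 30),
                   sex = c("F", "M"), C01 = c("a", "a"), A01 = c("0", "1")),
    items)
  fm <- encode_features(ch)
  expect_equal(unname(fm$values[, "C01=a"]), c(1, 1))

  ch_all_missing <- cohort(
    tibble::tibble(subject_id = c("s1", "s2"), age = c(20, 30),
                   sex = c("F", "M"), C01 = c("-9", "-9"), A01 = c("0", "1")),
    items)
  expect_error(encode_features(ch_all_missing), "C01")
})

test_that("complete-case filtering excludes subjects with absent responses", {
  items <- toy_items()
  tab <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"), age = c(30, 40, 50),
    sex = c("F", "M", "F"), A01 = c("0", NA, "1"), B01 = c("0", "2", "1")
  )
  expect_message(fm <- encode_features(cohort(tab, items)), "complete-case")
  expect_equal(fm$subject_ids, c("s1", "s3"))
})

test_that("encoded column count matches a brute-force recount on random cohorts", {
  withr::local_seed(42)
  for (rep in 1:5) {
    n_items <- sample(3:8, 1)
    kinds <- sample(c("binary", "ordinal", "categorical"), n_items,
                    replace = TRUE)
    av <- lapply(kinds, function(k) switch(k,
      binary = c("0", "1"), ordinal = as.character(0:3),
      categorical = letters[1:sample(2:4, 1)]))
    items <- item_definitions(
      sprintf("I%02d", 1:n_items),
      sample(LETTERS[1:8], n_items, replace = TRUE),
      kinds, av, missing_codes = as.list(rep("-9", n_items)))
    n <- 20
    resp <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                           age = 20 + 1:n, sex = rep(c("F", "M"), n / 2))
    for (i in 1:n_items) {
      resp[[items$item_id[i]]] <- sample(av[[i]], n, replace = TRUE)
    }
    fm <- encode_features(cohort(resp, items))
    expected <- sum(ifelse(kinds == "categorical", lengths(av), 1)) + 2
    expect_equal(ncol(fm$values), expected)
  }
})

test_that("standardization gives population z-scores and handles constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  fm <- features_from_matrix(m)
  expect_warning(z <- standardize(fm), "constant")
  expect_equal(unname(z$values[, "a"]),
               c(-1.22474487139159, 0, 1.22474487139159))
  expect_equal(unname(z$values[, "b"]), c(0, 0, 0))
  expect_true(z$standardized)
  expect_error(standardize(z), "already")
})

test_that("standardizing an already-centered matrix is a near no-op", {
  withr::local_seed(7)
  m <- matrix(rnorm(200), 40, 5)
  z1 <- standardize(features_from_matrix(m))
  z2 <- standardize(features_from_matrix(z1$values))
  expect_lt(max(abs(z1$values - z2$values)), 1e-10)
  # and columns are mean 0, population sd 1
  expect_lt(max(abs(colMeans(z1$values))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(sweep(z1$values, 2,
                                        colMeans(z1$values))^2)) - 1)), 1e-8)
})
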