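# Scale-threshold diagnosis rules and diagnosis-source comparison.
#
# A score-based diagnosis rule is a set of OR-combined clauses
# (scale, comparator, threshold): the diagnosis is assigned when any clause
# holds. The shipped default rule set uses clinician and self-report rating
# scales: depression from the Hamilton Depression Rating Scale (HAMD),
# anxiety from the Hamilton Anxiety Rating Scale (HAMA) or the Panic
# Disorder Severity Scale (PDSS), bipolar disorder from the Mood Disorder
# Questionnaire (MDQ) or the Hypomania Checklist (HCL-32).

#' Build a score-based diagnosis rule table
#'
#' @param diagnosis,scale,comparator,threshold Parallel vectors; one row per
#'   clause. Clauses of the same diagnosis are OR-combined. `comparator` is
#'   one of `">="`, `">"`, `"<="`, `"<"`.
#' @return A `transdx_rules` tibble.
#' @export
score_rules <- function(diagnosis, scale, comparator, threshold) {
  ok <- comparator %in% c(">=", ">", "<=", "<")
  if (!all(ok)) abort("comparator must be one of >=, >, <=, <")
  if (!all(is.finite(threshold))) abort("thresholds must be finite")
  rules <- tibble::tibble(
    diagnosis = as.character(diagnosis),
    scale = as.character(scale),
    comparator = as.character(comparator),
    threshold = as.numeric(threshold)
  )
  if (!nrow(rules)) abort("rule set must contain at least one clause")
  class(rules) <- c("transdx_rules", class(rules))
  rules
}

#' Default scale-threshold diagnosis rule set
#'
#' Depression: HAMD >= 7. Anxiety: HAMA >= 10 or PDSS >= 8.
#' Bipolar: MDQ >= 7 or HCL32 >= 12. Editable: build an alternative set with
#' [score_rules()] or load one from YAML/JSON via [read_score_rules()].
#'
#' @return A `transdx_rules` tibble.
#' @export
default_score_rules <- function() {
  score_rules(
    diagnosis  = c("depression", "anxiety", "anxiety", "bipolar", "bipolar"),
    scale      = c("HAMD", "HAMA", "PDSS", "MDQ", "HCL32"),
    comparator = rep(">=", 5),
    threshold  = c(7, 10, 8, 7, 12)
  )
}

#' Read a rule set from YAML or JSON
#'
#' Expects a list of records with fields `diagnosis`, `scale`, `comparator`,
#' `threshold`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `transdx_rules` tibble.
#' @export
read_score_rules <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  recs <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  score_rules(recs$diagnosis, recs$scale, recs$comparator, recs$threshold)
}

#' Per-subject diagnosis label sets
#'
#' @param subject_id Character vector (every cohort subject, labeled or not).
#' @param diagnoses List of character vectors (possibly empty) per subject.
#' @param source `"self_reported"` or `"score_based"`.
#' @return A `transdx_diagnoses` object.
#' @export
diagnosis_labels <- function(subject_id, diagnoses, source) {
  source <- match.arg(source, c("self_reported", "score_based"))
  stopifnot(length(subject_id) == length(diagnoses))
  structure(
    tibble::tibble(
      subject_id = as.character(subject_id),
      diagnoses = lapply(diagnoses, function(d) sort(unique(as.character(d))))
    ),
    source = source,
    class = c("transdx_diagnoses", "tbl_df", "tbl", "data.frame")
  )
}

#' Apply score-based diagnosis rules to a scale-score table
#'
#' A subject receives a diagnosis when any of its clauses holds. Missing
#' scale values make the clause evaluate to false (reported via a message).
#'
#' @param scale_scores Tibble with `subject_id` and one numeric column per
#'   scale referenced by `rules`.
#' @param rules A `transdx_rules` table; default [default_score_rules()].
#' @return A `transdx_diagnoses` object with source `"score_based"`.
#' @export
apply_score_diagnosis <- function(scale_scores, rules = default_score_rules()) {
  missing_scales <- setdiff(unique(rules$scale), names(scale_scores))
  if (length(missing_scales)) {
    abort(paste0("scale(s) referenced by rules absent from score table: ",
                 paste(missing_scales, collapse = ", ")))
  }
  n <- nrow(scale_scores)
  hits <- matrix(FALSE, n, length(unique(rules$diagnosis)),
                 dimnames = list(NULL, unique(rules$diagnosis)))
  n_missing <- 0L
  for (j in seq_len(nrow(rules))) {
    x <- as.numeric(scale_scores[[rules$scale[j]]])
    miss <- is.na(x)
    n_missing <- n_missing + sum(miss)
    fire <- switch(rules$comparator[j],
      ">=" = x >= rules$threshold[j],
      ">"  = x >  rules$threshold[j],
      "<=" = x <= rules$threshold[j],
      "<"  = x <  rules$threshold[j]
    )
    fire[miss] <- FALSE
    hits[, rules$diagnosis[j]] <- hits[, rules$diagnosis[j]] | fire
  }
  if (n_missing > 0) {
    inform(paste0(n_missing, " missing scale value(s); affected clauses",
                  " evaluated as false"))
  }
  diagnosis_labels(
    scale_scores$subject_id,
    lapply(seq_len(n), function(i) colnames(hits)[hits[i, ]]),
    source = "score_based"
  )
}

#' Compare two diagnosis label sources
#'
#' Subjects agree when their label sets, restricted to the comparison
#' vocabulary, are identical. The default vocabulary is the intersection of
#' the diagnoses observed in either source (labels only one source can
#' express are not counted as disagreement); `vocabulary = "union"` compares
#' over all observed diagnoses.
#'
#' @param a,b `transdx_diagnoses` over the same subject universe.
#' @param vocabulary `"shared"` (default) or `"union"`.
#' @return A `transdx_dx_comparison`: per-subject agreement flags, the
#'   overall inconsistency rate, and per-diagnosis confusion counts.
#' @export
compare_diagnoses <- function(a, b, vocabulary = c("shared", "union")) {
  vocabulary <- match.arg(vocabulary)
  if (!setequal(a$subject_id, b$subject_id)) {
    abort("diagnosis sources cover different subject universes")
  }
  b <- b[match(a$subject_id, b$subject_id), ]
  vocab_a <- unique(unlist(a$diagnoses))
  vocab_b <- unique(unlist(b$diagnoses))
  vocab <- if (vocabulary == "shared") intersect(vocab_a, vocab_b) else
    union(vocab_a, vocab_b)
  if (!length(vocab)) {
    abort("diagnosis vocabularies are disjoint; nothing comparable")
  }
  set_a <- lapply(a$diagnoses, intersect, x = vocab)
  set_b <- lapply(b$diagnoses, intersect, x = vocab)
  agree <- mapply(setequal, set_a, set_b)
  per_subject <- tibble::tibble(
    subject_id = a$subject_id,
    labels_a = vapply(set_a, paste, "", collapse = ";"),
    labels_b = vapply(set_b, paste, "", collapse = ";"),
    agree = as.logical(agree)
  )
  confusion <- purrr::map_dfr(vocab, function(d) {
    ina <- vapply(set_a, function(s) d %in% s, TRUE)
    inb <- vapply(set_b, function(s) d %in% s, TRUE)
    tibble::tibble(
      diagnosis = d,
      both = sum(ina & inb), a_only = sum(ina & !inb),
      b_only = sum(!ina & inb), neither = sum(!ina & !inb)
    )
  })
  structure(
    list(
      per_subject = per_subject,
      inconsistency_rate = mean(!agree),
      confusion = confusion,
      vocabulary = vocab
    ),
    class = "transdx_dx_comparison"
  )
}

#' @export
print.transdx_dx_comparison <- function(x, ...) {
  cat("<transdx_dx_comparison> ", nrow(x$per_subject), " subjects, ",
      sprintf("%.2f%%", 100 * x$inconsistency_rate), " inconsistent\n",
      sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
#' @exportS3Method generics::glance
glance.transdx_dx_comparison <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$per_subject),
    n_diagnoses = nrow(x$confusion),
    inconsistency_rate = x$inconsistency_rate
  )
}

#' @export
#' @exportS3Method generics::tidy
tidy.transdx_dx_comparison <- function(x, ...) x$per_subject
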