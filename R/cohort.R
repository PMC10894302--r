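# Cohort container and delimited-file I/O.
#
# A cohort bundles three tibbles: per-subject demographics (subject_id, age,
# sex), raw coded responses (subject_id + one character column per item), and
# the item metadata table that assigns every item to a symptom category A-H
# and declares its value kind and legal codes.

#' Construct an item metadata table
#'
#' Every questionnaire item carries a category (the eight topic blocks A-H:
#' diagnostic screening, mood disorder, anxiety, general/drug addiction,
#' alcohol and cannabis use, unusual/psychotic experiences, traumatic events,
#' harmful behaviours), a value kind and the ordered list of legal codes.
#' Codes in `missing_codes` (e.g. "prefer not to answer") are legal in the
#' response table but are treated as missing by the encoders.
#'
#' @param item_id Character vector of unique item identifiers.
#' @param category Character vector in `LETTERS[1:8]`.
#' @param value_kind One of `"binary"`, `"ordinal"`, `"categorical"`,
#'   `"continuous"` per item.
#' @param allowed_values List of character vectors, ordered, one per item.
#' @param missing_codes List of character vectors (may be empty), one per
#'   item; must be disjoint from `allowed_values`.
#' @param text Optional item wording.
#' @return A tibble with list-columns `allowed_values` and `missing_codes`.
#' @export
item_definitions <- function(item_id, category, value_kind, allowed_values,
                             missing_codes = NULL, text = NULL) {
  n <- length(item_id)
  missing_codes <- missing_codes %||% rep(list(character()), n)
  text <- text %||% item_id
  items <- tibble::tibble(
    item_id = as.character(item_id),
    text = as.character(text),
    category = as.character(category),
    value_kind = as.character(value_kind),
    allowed_values = lapply(allowed_values, as.character),
    missing_codes = lapply(missing_codes, as.character)
  )
  validate_items(items)
}

validate_items <- function(items) {
  if (anyDuplicated(items$item_id)) {
    abort(paste0("duplicate item_id: ",
                 paste(unique(items$item_id[duplicated(items$item_id)]),
                       collapse = ", ")))
  }
  bad_cat <- setdiff(unique(items$category), LETTERS[1:8])
  if (length(bad_cat)) {
    abort(paste0("item category must be one of A-H; got: ",
                 paste(bad_cat, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(items$value_kind),
                      c("binary", "ordinal", "categorical", "continuous"))
  if (length(bad_kind)) {
    abort(paste0("unknown value_kind: ", paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(items))) {
    av <- items$allowed_values[[i]]
    mc <- items$missing_codes[[i]]
    if (!length(av)) {
      abort(paste0("item ", items$item_id[i], ": allowed_values is empty"))
    }
    if (length(intersect(av, mc))) {
      abort(paste0("item ", items$item_id[i],
                   ": missing_codes overlap allowed_values"))
    }
  }
  items
}

#' Construct a cohort from in-memory tables
#'
#' @param responses Tibble with columns `subject_id`, `age`, `sex` and one
#'   character-coded column per item in `items`.
#' @param items Item metadata from [item_definitions()].
#' @return A validated `transdx_cohort`.
#' @export
cohort <- function(responses, items) {
  items <- validate_items(items)
  for (col in c("subject_id", "age", "sex")) {
    if (!col %in% names(responses)) {
      abort(paste0("responses table lacks required column `", col, "`"))
    }
  }
  responses <- tibble::as_tibble(responses)
  responses$subject_id <- trimws(as.character(responses$subject_id))

  bad_id <- is.na(responses$subject_id) | responses$subject_id == "" |
    responses$subject_id == "NA"
  if (any(bad_id)) {
    inform(paste0("rejected ", sum(bad_id), " row(s) with malformed subject id"))
    responses <- responses[!bad_id, , drop = FALSE]
  }
  if (anyDuplicated(responses$subject_id)) {
    dups <- unique(responses$subject_id[duplicated(responses$subject_id)])
    abort(paste0("duplicate subject id(s): ", paste(dups, collapse = ", ")))
  }

  item_cols <- setdiff(names(responses), c("subject_id", "age", "sex"))
  uncovered <- setdiff(item_cols, items$item_id)
  if (length(uncovered)) {
    abort(paste0("response column(s) without item metadata: ",
                 paste(uncovered, collapse = ", ")))
  }
  items <- items[items$item_id %in% item_cols, , drop = FALSE]

  resp <- responses[, c("subject_id", items$item_id), drop = FALSE]
  resp[items$item_id] <- lapply(resp[items$item_id], as.character)
  for (i in seq_len(nrow(items))) {
    id <- items$item_id[i]
    legal <- c(items$allowed_values[[i]], items$missing_codes[[i]])
    v <- resp[[id]]
    bad <- !is.na(v) & !(v %in% legal)
    if (any(bad)) {
      w <- which(bad)[1]
      abort(paste0("unknown response code \"", v[w], "\" for item ", id,
                   " (subject ", resp$subject_id[w], ")"))
    }
  }

  structure(
    list(
      subjects = tibble::tibble(
        subject_id = responses$subject_id,
        age = as.numeric(responses$age),
        sex = as.character(responses$sex)
      ),
      responses = resp,
      items = items
    ),
    class = "transdx_cohort"
  )
}

#' Read a cohort from responses and item-metadata files
#'
#' Files are UTF-8 delimited text (comma for `.csv`, tab otherwise), first
#' row a header, lines starting with `#` skipped. The responses file needs
#' `subject_id`, `age`, `sex` plus one column per item; the items file needs
#' `item_id`, `category`, `value_kind`, `allowed_values` and `missing_codes`
#' with code lists joined by `,`.
#'
#' Rows with malformed (empty/NA) subject ids are dropped with a message;
#' duplicated subject ids and response codes outside an item's legal set are
#' errors.
#'
#' @param responses_path,items_path Paths to the two files.
#' @return A `transdx_cohort`.
#' @export
load_cohort <- function(responses_path, items_path) {
  responses <- read_table_auto(responses_path)
  raw_items <- read_table_auto(items_path)
  for (col in c("item_id", "category", "value_kind", "allowed_values")) {
    if (!col %in% names(raw_items)) {
      abort(paste0("items file lacks required column `", col, "`"))
    }
  }
  split_codes <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
    })
  }
  items <- item_definitions(
    item_id = raw_items$item_id,
    category = raw_items$category,
    value_kind = raw_items$value_kind,
    allowed_values = split_codes(as.character(raw_items$allowed_values)),
    missing_codes = if ("missing_codes" %in% names(raw_items)) {
      split_codes(as.character(raw_items$missing_codes))
    } else NULL,
    text = if ("text" %in% names(raw_items)) raw_items$text else NULL
  )
  cohort(responses, items)
}

#' Write a cohort to `responses.tsv` and `items.tsv`
#'
#' Inverse of [load_cohort()]; both files carry a schema-version header
#' comment.
#'
#' @param x A `transdx_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "transdx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  resp <- dplyr::left_join(x$subjects, x$responses, by = "subject_id")
  join <- function(l) vapply(l, paste, "", collapse = ",")
  items <- tibble::tibble(
    item_id = x$items$item_id,
    text = x$items$text,
    category = x$items$category,
    value_kind = x$items$value_kind,
    allowed_values = join(x$items$allowed_values),
    missing_codes = join(x$items$missing_codes)
  )
  paths <- c(file.path(dir, "responses.tsv"), file.path(dir, "items.tsv"))
  write_table_auto(resp, paths[1])
  write_table_auto(items, paths[2])
  invisible(paths)
}

#' @export
print.transdx_cohort <- function(x, ...) {
  cat("<transdx_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$items), " items in ",
      length(unique(x$items$category)), " categories\n", sep = "")
  invisible(x)
}

#' Long-format view of cohort responses
#'
#' @param x A `transdx_cohort`.
#' @param ... Unused.
#' @return Tibble with one row per subject-item response.
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_cohort <- function(x, ...) {
  x$responses |>
    tidyr::pivot_longer(-"subject_id", names_to = "item_id",
                        values_to = "code") |>
    dplyr::left_join(
      dplyr::select(x$items, "item_id", "category", "value_kind"),
      by = "item_id"
    )
}
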