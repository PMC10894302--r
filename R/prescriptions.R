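# Prescription records and the drug -> class curation map.
#
# "Labeled" subjects are exactly those present in the prescription table;
# both recommendation engines and their evaluation key on this.

#' Construct prescription records from subject/class pairs
#'
#' @param subject_id,class Parallel vectors, one row per held class;
#'   duplicates collapse.
#' @param classes Class vocabulary, default [default_drug_classes()].
#' @param rejected Optional tibble of unmapped (subject_id, drug_name) rows.
#' @return A `transdx_prescriptions` object.
#' @export
prescriptions <- function(subject_id, class,
                          classes = default_drug_classes(),
                          rejected = NULL) {
  bad <- setdiff(unique(class), classes)
  if (length(bad)) {
    abort(paste0("drug class(es) outside vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  tab <- dplyr::distinct(tibble::tibble(
    subject_id = as.character(subject_id),
    class = as.character(class)
  ))
  structure(
    list(
      classes = dplyr::arrange(tab, .data$subject_id, .data$class),
      subjects = sort(unique(tab$subject_id)),
      vocabulary = classes,
      rejected = rejected %||%
        tibble::tibble(subject_id = character(), drug_name = character())
    ),
    class = "transdx_prescriptions"
  )
}

#' Read a prescription table and map drugs to classes
#'
#' The file holds one row per (subject, drug): columns `subject_id` and
#' `drug_name`. Drug names are lower-cased and trimmed before lookup in the
#' curation map; names absent from the map are collected into the
#' `rejected` report (never silently dropped) and the subject is retained
#' with its mapped drugs only. Per-subject class sets are deduplicated.
#'
#' @param path Delimited file path.
#' @param class_map Named character vector or two-column data frame
#'   (`drug_name`, `class`) mapping curated drug names to classes.
#' @param classes Class vocabulary the map must draw from.
#' @return A `transdx_prescriptions` object.
#' @export
load_prescriptions <- function(path, class_map,
                               classes = default_drug_classes()) {
  if (is.data.frame(class_map)) {
    class_map <- setNames(as.character(class_map[[2]]),
                          as.character(class_map[[1]]))
  }
  if (!length(class_map)) abort("class_map is empty")
  names(class_map) <- trimws(tolower(names(class_map)))
  bad <- setdiff(unique(unname(class_map)), classes)
  if (length(bad)) {
    abort(paste0("class_map value(s) outside vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  tab <- read_table_auto(path)
  for (col in c("subject_id", "drug_name")) {
    if (!col %in% names(tab)) {
      abort(paste0("prescription file lacks required column `", col, "`"))
    }
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$drug_name <- trimws(tolower(as.character(tab$drug_name)))
  mapped <- tab$drug_name %in% names(class_map)
  rejected <- dplyr::distinct(tab[!mapped, c("subject_id", "drug_name")])
  if (nrow(rejected)) {
    inform(paste0(nrow(rejected), " prescription row(s) with unmapped drug",
                  " name(s) collected in the rejection report"))
  }
  kept <- tab[mapped, , drop = FALSE]
  prescriptions(
    subject_id = kept$subject_id,
    class = unname(class_map[kept$drug_name]),
    classes = classes,
    rejected = rejected
  )
}

#' Per-subject class sets as a list
#'
#' @param rx A `transdx_prescriptions`.
#' @return Named list subject_id -> character vector of classes.
#' @export
prescription_sets <- function(rx) {
  split(rx$classes$class, rx$classes$subject_id)
}

#' @export
print.transdx_prescriptions <- function(x, ...) {
  cat("<transdx_prescriptions> ", length(x$subjects), " labeled subjects, ",
      nrow(x$classes), " subject-class pairs",
      if (nrow(x$rejected)) paste0(" (", nrow(x$rejected), " rejected rows)"),
      "\n", sep = "")
  invisible(x)
}

#' Long subject/class table
#'
#' @param x A `transdx_prescriptions`.
#' @param ... Unused.
#' @return Tibble (subject_id, class).
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_prescriptions <- function(x, ...) x$classes
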