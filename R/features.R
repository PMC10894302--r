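# Feature encoding and standardization.
#
# Mixed-type questionnaire items become a dense numeric matrix: categorical
# items are one-hot encoded (optionally dropping the indicators of
# missing-value codes, which carry no symptom information), binary and
# ordinal items map to a single column by code position, continuous items
# are taken at face value, and age and sex are appended. Subjects with any
# remaining absent value are excluded (complete-case analysis).

#' Encode a cohort to a numeric feature matrix
#'
#' @param cohort A `transdx_cohort`.
#' @param drop_missing_indicators Drop the one-hot columns that indicate
#'   "prefer not to answer"/unknown codes of categorical items (default
#'   `TRUE`). When dropped, a subject holding such a code gets zeros across
#'   the item's remaining indicators.
#' @return A `transdx_features` object: subjects x features numeric matrix
#'   with a `provenance` tibble mapping every feature back to its item and
#'   encoding role.
#' @details Binary and ordinal items are encoded as one column each (code
#'   position in the item's ordered `allowed_values`, zero-based), which
#'   preserves response ordering; only genuinely categorical items are
#'   expanded to indicators. Missing-code responses of single-column items
#'   cannot be scored and leave the subject incomplete. Subjects excluded by
#'   complete-case filtering are reported via a message.
#' @export
encode_features <- function(cohort, drop_missing_indicators = TRUE) {
  stopifnot(inherits(cohort, "transdx_cohort"))
  items <- cohort$items
  resp <- cohort$responses
  n <- nrow(resp)

  cols <- list()
  prov <- list()
  for (i in seq_len(nrow(items))) {
    id <- items$item_id[i]
    av <- items$allowed_values[[i]]
    mc <- items$missing_codes[[i]]
    v <- resp[[id]]
    observed <- !is.na(v) & !(v %in% mc)
    if (!any(observed)) {
      abort(paste0("item ", id, " has zero observed non-missing values"))
    }
    kind <- items$value_kind[i]
    if (kind == "categorical") {
      levels <- if (drop_missing_indicators) av else c(av, mc)
      for (lev in levels) {
        nm <- paste0(id, "=", lev)
        col <- ifelse(is.na(v), NA_real_, as.numeric(v == lev))
        cols[[nm]] <- col
        prov[[nm]] <- c(id, paste0("indicator:", lev))
      }
    } else {
      if (kind == "continuous") {
        num <- suppressWarnings(as.numeric(v))
      } else {
        num <- as.numeric(match(v, av) - 1L)
      }
      num[!is.na(v) & v %in% mc] <- NA_real_
      cols[[id]] <- num
      prov[[id]] <- c(id, "numeric")
    }
  }

  cols[["age"]] <- cohort$subjects$age
  prov[["age"]] <- c(NA_character_, "demographic")
  sex_levels <- sort(unique(stats::na.omit(cohort$subjects$sex)))
  if (length(sex_levels) > 2) {
    abort("sex column has more than two distinct codes")
  }
  cols[["sex"]] <- as.numeric(cohort$subjects$sex == sex_levels[length(sex_levels)])
  prov[["sex"]] <- c(NA_character_, "demographic")

  m <- do.call(cbind, cols)
  rownames(m) <- resp$subject_id

  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    inform(paste0("excluded ", sum(!complete),
                  " subject(s) with missing values (complete-case)"))
    m <- m[complete, , drop = FALSE]
  }

  provenance <- tibble::tibble(
    feature = names(prov),
    item_id = vapply(prov, `[`, "", 1L),
    role = vapply(prov, `[`, "", 2L)
  )
  new_features(m, provenance, standardized = FALSE)
}

new_features <- function(m, provenance, standardized) {
  structure(
    list(
      subject_ids = rownames(m),
      values = m,
      provenance = provenance,
      standardized = standardized
    ),
    class = "transdx_features"
  )
}

#' Standard-scale a feature matrix
#'
#' Centers and scales each column to mean 0 and unit population standard
#' deviation. Constant columns (zero variance) are set to 0 with a warning
#' rather than producing non-finite values.
#'
#' @param fm A non-standardized `transdx_features`.
#' @return The standardized `transdx_features`.
#' @export
standardize <- function(fm) {
  stopifnot(inherits(fm, "transdx_features"))
  if (fm$standardized) {
    abort("feature matrix is already standardized")
  }
  m <- fm$values
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population sd
  constant <- sdev < 1e-12
  if (any(constant)) {
    warn(paste0(sum(constant), " constant feature column(s) set to 0: ",
                paste(head(colnames(m)[constant], 5), collapse = ", ")))
  }
  scale_by <- ifelse(constant, 1, sdev)
  z <- sweep(sweep(m, 2, mu), 2, scale_by, "/")
  z[, constant] <- 0
  new_features(z, fm$provenance, standardized = TRUE)
}

#' @export
print.transdx_features <- function(x, ...) {
  cat("<transdx_features> ", nrow(x$values), " subjects x ",
      ncol(x$values), " features",
      if (x$standardized) " (standardized)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.transdx_features <- function(x) dim(x$values)

#' Feature matrix as a tibble
#'
#' @param x A `transdx_features`.
#' @param ... Unused.
#' @return Tibble with `subject_id` and one column per feature.
#' @export
#' @exportS3Method generics::tidy
tidy.transdx_features <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids),
    tibble::as_tibble(x$values)
  )
}
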