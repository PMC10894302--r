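# Shared internal helpers: file dialect detection, schema-tagged writers,
# seeded RNG scoping, competition ranking.

SCHEMA_VERSION <- "transdx-schema-1"

#' Default drug-class vocabulary
#'
#' Psychotropic drug classes used throughout the package: antidepressants
#' (AD), antipsychotics (AP), mood stabilizers (MS) and sedative-hypnotics
#' (SH). All class-level operations accept an extended vocabulary (e.g. an
#' extra OTHER class) via their `classes` argument.
#'
#' @return Character vector of class codes.
#' @export
default_drug_classes <- function() c("AD", "AP", "MS", "SH")

# Delimited reader: dialect chosen by extension (.csv -> comma, else tab),
# UTF-8, first row header, "#"-prefixed schema/comment lines skipped.
read_table_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  reader(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

# Writer emitting a schema-versioned header comment before the body.
write_table_auto <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  writeLines(paste0("# ", SCHEMA_VERSION), path)
  readr::write_delim(x, path, delim = delim, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Competition ("1224") ranking of values in *descending* order: tied values
# share the smallest rank of their tie group; next rank is offset by the
# group size.
competition_rank <- function(x) {
  as.integer(rank(-x, ties.method = "min"))
}

stopifnot_scalar_int <- function(x, name, lower = -Inf) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < lower) {
    abort(paste0("`", name, "` must be a single integer >= ", lower))
  }
  as.integer(x)
}
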