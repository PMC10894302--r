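# Synthetic cohort generator.
#
# Emulates the structure of a mental-health questionnaire cohort: mixed-type
# items organised in the eight topic categories A-H, latent symptom
# subgroups that elevate category-specific responses, scale scores that
# drive score-based diagnoses, and a sparse prescription table with
# group-conditional drug-class probabilities. Items are conditionally
# independent given the latent group (deliberately simple: enough structure
# to exercise and validate every pipeline stage with known ground truth).

#' Build a synthetic cohort configuration
#'
#' @param n_subjects Number of subjects.
#' @param n_groups Number of latent symptom groups.
#' @param group_weights Group mixing proportions (simplex; default uniform).
#' @param elevation `n_groups x 8` matrix (columns A-H) of per-group
#'   per-category response elevations, in latent-sigma units. Ordinal,
#'   categorical and continuous items shift their latent normal mean by the
#'   elevation; binary items shift their success probability by
#'   `elevation / 10` (so an 8-sigma elevation is a +0.8 probability shift),
#'   clamped to `[0.01, 0.99]`.
#' @param n_items Named integer vector: items per category A-H.
#' @param labeled_fraction Expected share of subjects with prescription
#'   records (default 0.09, the sparse-label regime of large biobank
#'   questionnaire cohorts).
#' @param class_probs `n_groups x length(classes)` matrix of per-group
#'   drug-class prescription probabilities.
#' @param classes Drug-class vocabulary.
#' @param scale_means `n_groups x 5` matrix of mean scale scores
#'   (columns HAMD, HAMA, PDSS, MDQ, HCL32) for [generate_scale_scores()].
#' @param age_range Uniform age window in years.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A validated `transdx_syncfg` list.
#' @export
synthetic_config <- function(n_subjects, n_groups,
                             group_weights = NULL,
                             elevation = NULL,
                             n_items = NULL,
                             labeled_fraction = 0.09,
                             class_probs = NULL,
                             classes = default_drug_classes(),
                             scale_means = NULL,
                             age_range = c(40, 70),
                             seed = 1) {
  n_subjects <- stopifnot_scalar_int(n_subjects, "n_subjects", 1)
  n_groups <- stopifnot_scalar_int(n_groups, "n_groups", 1)
  group_weights <- group_weights %||% rep(1 / n_groups, n_groups)
  if (length(group_weights) != n_groups ||
      abs(sum(group_weights) - 1) > 1e-8 || any(group_weights < 0)) {
    abort("group_weights must be a length-n_groups simplex vector")
  }
  elevation <- elevation %||% matrix(0, n_groups, 8)
  colnames(elevation) <- LETTERS[1:8]
  stopifnot(nrow(elevation) == n_groups, ncol(elevation) == 8)
  n_items <- n_items %||% setNames(rep(5L, 8), LETTERS[1:8])
  stopifnot(length(n_items) == 8)
  names(n_items) <- LETTERS[1:8]
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    abort("labeled_fraction must be in (0, 1]")
  }
  class_probs <- class_probs %||%
    matrix(rep(c(0.75, 0.03, 0.08, 0.10), each = n_groups), n_groups, 4)
  colnames(class_probs) <- classes
  stopifnot(nrow(class_probs) == n_groups,
            ncol(class_probs) == length(classes))
  if (any(class_probs < 0 | class_probs > 1)) {
    abort("class_probs must lie in [0, 1]")
  }
  scale_means <- scale_means %||%
    matrix(rep(c(4, 5, 2, 3, 5), each = n_groups), n_groups, 5)
  colnames(scale_means) <- c("HAMD", "HAMA", "PDSS", "MDQ", "HCL32")
  structure(
    list(
      n_subjects = n_subjects, n_groups = n_groups,
      group_weights = group_weights, elevation = elevation,
      n_items = n_items, labeled_fraction = labeled_fraction,
      class_probs = class_probs, classes = classes,
      scale_means = scale_means, age_range = age_range,
      seed = as.integer(seed)
    ),
    class = "transdx_syncfg"
  )
}

# item kinds cycle within each category so every encoder path is exercised
synthetic_item_kinds <- c("binary", "ordinal", "binary", "ordinal",
                          "categorical")

synthetic_items <- function(cfg) {
  rows <- list()
  for (cat in LETTERS[1:8]) {
    for (j in seq_len(cfg$n_items[[cat]])) {
      kind <- synthetic_item_kinds[1 + (j - 1) %% length(synthetic_item_kinds)]
      rows[[length(rows) + 1]] <- list(
        item_id = sprintf("%s%02d", cat, j),
        category = cat,
        value_kind = kind,
        allowed_values = switch(kind,
          binary = c("0", "1"),
          ordinal = as.character(0:4),
          categorical = c("a", "b", "c")
        ),
        missing_codes = "-9"
      )
    }
  }
  item_definitions(
    item_id = vapply(rows, `[[`, "", "item_id"),
    category = vapply(rows, `[[`, "", "category"),
    value_kind = vapply(rows, `[[`, "", "value_kind"),
    allowed_values = lapply(rows, `[[`, "allowed_values"),
    missing_codes = lapply(rows, `[[`, "missing_codes")
  )
}

#' Generate a synthetic cohort with known latent structure
#'
#' Subjects are drawn into latent groups by the configured weights; binary
#' items are Bernoulli with a group-and-category-dependent probability,
#' ordinal and categorical items discretize a shifted standard normal at
#' equal-width cut points, age is uniform in the configured window and sex
#' Bernoulli(0.5). Fully reproducible from the config seed.
#'
#' @param cfg A `transdx_syncfg`.
#' @return List with `cohort` (a `transdx_cohort`) and `truth` (a
#'   `transdx_truth`: per-subject latent group plus the generating
#'   parameters; never written into pipeline input files).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "transdx_syncfg"))
  n <- cfg$n_subjects
  if (cfg$n_groups > n) abort("n_groups exceeds n_subjects")
  items <- synthetic_items(cfg)
  with_seed(cfg$seed, {
    group <- sample.int(cfg$n_groups, n, replace = TRUE,
                        prob = cfg$group_weights)
    subject_id <- sprintf("S%06d", seq_len(n))
    resp <- list(subject_id = subject_id)
    for (i in seq_len(nrow(items))) {
      cat <- items$category[i]
      e <- cfg$elevation[group, cat]
      kind <- items$value_kind[i]
      if (kind == "binary") {
        p <- pmin(pmax(0.15 + e / 10, 0.01), 0.99)
        resp[[items$item_id[i]]] <- as.character(stats::rbinom(n, 1, p))
      } else {
        latent <- stats::rnorm(n, mean = e, sd = 1)
        n_levels <- length(items$allowed_values[[i]])
        cuts <- seq(-1.5, 1.5, length.out = n_levels - 1)
        code <- findInterval(latent, cuts)  # 0 .. n_levels - 1
        resp[[items$item_id[i]]] <- items$allowed_values[[i]][code + 1L]
      }
    }
    resp <- tibble::as_tibble(resp)
    resp$age <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
    resp$sex <- c("F", "M")[1 + stats::rbinom(n, 1, 0.5)]
    truth <- structure(
      list(
        groups = tibble::tibble(subject_id = subject_id, group = group),
        class_probs = cfg$class_probs,
        elevation = cfg$elevation
      ),
      class = "transdx_truth"
    )
    list(cohort = cohort(resp, items), truth = truth)
  })
}

#' Generate scale scores consistent with the latent groups
#'
#' Scores are rounded normals around the per-group configured scale means
#' (sd 2), truncated at zero — enough signal for the score-based rule
#' engine to separate groups with distinct mean profiles.
#'
#' @param truth `transdx_truth` from [generate_cohort()].
#' @param cfg The same `transdx_syncfg`.
#' @return Tibble (subject_id, HAMD, HAMA, PDSS, MDQ, HCL32).
#' @export
generate_scale_scores <- function(truth, cfg) {
  g <- truth$groups$group
  with_seed(cfg$seed + 1L, {
    out <- tibble::tibble(subject_id = truth$groups$subject_id)
    for (s in colnames(cfg$scale_means)) {
      out[[s]] <- pmax(0, round(stats::rnorm(
        length(g), mean = cfg$scale_means[g, s], sd = 2)))
    }
    out
  })
}

#' Generate sparse group-conditional prescription records
#'
#' A seeded Bernoulli(`labeled_fraction`) draw selects the labeled subjects;
#' each labeled subject receives every class independently with its group's
#' probability. Subjects ending with no class are re-drawn once and, if
#' still empty, assigned their group's modal class, so every labeled
#' subject holds at least one class (fallback count reported).
#'
#' @param truth `transdx_truth` from [generate_cohort()].
#' @param cfg The same `transdx_syncfg`.
#' @return A `transdx_prescriptions`.
#' @export
generate_prescriptions <- function(truth, cfg) {
  g <- truth$groups$group
  n <- length(g)
  probs <- cfg$class_probs
  with_seed(cfg$seed + 2L, {
    labeled <- stats::rbinom(n, 1, cfg$labeled_fraction) == 1
    idx <- which(labeled)
    draw <- function(i) {
      stats::rbinom(ncol(probs), 1, probs[g[i], ]) == 1
    }
    n_fallback <- 0L
    pairs <- purrr::map(idx, function(i) {
      held <- draw(i)
      if (!any(held)) held <- draw(i)
      if (!any(held)) {
        n_fallback <<- n_fallback + 1L
        held <- seq_len(ncol(probs)) == which.max(probs[g[i], ])
      }
      tibble::tibble(subject_id = truth$groups$subject_id[i],
                     class = cfg$classes[held])
    })
    if (n_fallback > 0) {
      inform(paste0(n_fallback,
                    " labeled subject(s) assigned the modal-class fallback"))
    }
    tab <- dplyr::bind_rows(pairs)
    prescriptions(tab$subject_id, tab$class, classes = cfg$classes)
  })
}

#' Synthetic drug formulary (drug name -> class curation map)
#'
#' A small synthetic formulary used by [write_prescriptions()] so generated
#' prescription files round-trip through [load_prescriptions()].
#'
#' @return Named character vector drug name -> class.
#' @export
synthetic_class_map <- function() {
  c(
    fluoxetine = "AD", sertraline = "AD", citalopram = "AD",
    quetiapine = "AP", olanzapine = "AP", risperidone = "AP",
    lithium = "MS", valproate = "MS", lamotrigine = "MS",
    zopiclone = "SH", diazepam = "SH", zolpidem = "SH"
  )
}

#' Write prescription records as a (subject, drug) table
#'
#' Each subject-class pair is materialized as a drug name drawn
#' deterministically (round-robin) from the synthetic formulary of that
#' class; the schema round-trips through [load_prescriptions()] with
#' [synthetic_class_map()].
#'
#' @param rx A `transdx_prescriptions`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prescriptions <- function(rx, path) {
  map <- synthetic_class_map()
  by_class <- split(names(map), unname(map))
  tab <- rx$classes
  drug <- character(nrow(tab))
  for (cl in unique(tab$class)) {
    i <- which(tab$class == cl)
    pool <- by_class[[cl]] %||% paste0(tolower(cl), "_drug")
    drug[i] <- pool[1 + (seq_along(i) - 1) %% length(pool)]
  }
  write_table_auto(
    tibble::tibble(subject_id = tab$subject_id, drug_name = drug), path)
}

#' Named synthetic scenario presets
#'
#' * `"separable-4"` — four strongly separated groups (8-sigma category
#'   elevations, two signature categories per group), 40 items, 20% labeled;
#'   for recovery tests.
#' * `"ukbb-like"` — six moderately separated groups, 141 items in eight
#'   categories, 9% labeled, AD-dominant class skew; emulates the scale and
#'   sparsity of a biobank mental-health questionnaire.
#' * `"flat-null"` — a single group with no structure; for false-positive
#'   checks.
#'
#' @param name Preset name; an unknown name errors listing the options.
#' @param n Optional override of `n_subjects`.
#' @param seed Optional override of the seed.
#' @return A `transdx_syncfg`.
#' @export
scenario <- function(name, n = NULL, seed = NULL) {
  lib <- scenario_library()
  if (!name %in% names(lib)) {
    abort(paste0("unknown preset \"", name, "\"; available: ",
                 paste(names(lib), collapse = ", ")))
  }
  cfg <- lib[[name]]
  if (!is.null(n)) cfg$n_subjects <- stopifnot_scalar_int(n, "n", 1)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' @rdname scenario
#' @return For `scenario_library()`, the named list of all presets.
#' @export
scenario_library <- function() {
  sig_elev <- function(n_groups, strength, cats_per_group = 2) {
    e <- matrix(0, n_groups, 8)
    for (g in seq_len(n_groups)) {
      cats <- ((g - 1) * cats_per_group + seq_len(cats_per_group) - 1) %% 8 + 1
      e[g, cats] <- strength
    }
    e
  }
  list(
    "separable-4" = synthetic_config(
      n_subjects = 2000, n_groups = 4,
      elevation = sig_elev(4, 8),
      n_items = setNames(rep(5L, 8), LETTERS[1:8]),
      labeled_fraction = 0.20,
      class_probs = rbind(
        c(0.75, 0.03, 0.08, 0.10),
        c(0.60, 0.10, 0.20, 0.15),
        c(0.70, 0.25, 0.05, 0.40),
        c(0.80, 0.02, 0.10, 0.05)
      ),
      scale_means = rbind(
        c(12, 5, 2, 3, 5),    # depressive profile
        c(4, 14, 10, 3, 5),   # anxious profile
        c(10, 8, 3, 10, 14),  # mixed-mood profile
        c(2, 3, 1, 2, 4)      # low-symptom profile
      ),
      seed = 1
    ),
    "ukbb-like" = synthetic_config(
      n_subjects = 10000, n_groups = 6,
      elevation = sig_elev(6, 3) + sig_elev(6, 1.5, cats_per_group = 1),
      n_items = setNames(c(18L, 18L, 18L, 18L, 18L, 17L, 17L, 17L),
                         LETTERS[1:8]),
      labeled_fraction = 0.09,
      class_probs = rbind(
        c(0.78, 0.02, 0.15, 0.08),
        c(0.80, 0.03, 0.05, 0.10),
        c(0.75, 0.05, 0.10, 0.15),
        c(0.72, 0.03, 0.08, 0.10),
        c(0.55, 0.30, 0.20, 0.16),  # psychosis-like: AP concentrated here
        c(0.76, 0.02, 0.08, 0.35)   # sleep-problem-like: SH elevated
      ),
      scale_means = rbind(
        c(12, 6, 2, 3, 5),
        c(5, 13, 9, 3, 5),
        c(9, 8, 3, 10, 14),
        c(3, 3, 1, 2, 4),
        c(8, 9, 4, 6, 8),
        c(7, 10, 3, 3, 5)
      ),
      seed = 1
    ),
    "flat-null" = synthetic_config(
      n_subjects = 2000, n_groups = 1,
      elevation = matrix(0, 1, 8),
      n_items = setNames(rep(5L, 8), LETTERS[1:8]),
      labeled_fraction = 0.09,
      class_probs = matrix(c(0.76, 0.03, 0.08, 0.10), 1, 4),
      scale_means = matrix(c(6, 7, 3, 4, 6), 1, 5),
      seed = 1
    )
  )
}
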