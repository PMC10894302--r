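# End-to-end pipeline driver: simulate/load -> preprocess -> profile ->
# characterize -> recommend -> evaluate, with per-stage provenance and a
# single aggregated JSON run report.

#' Build a pipeline run configuration
#'
#' Either a synthetic preset (`preset`, `n`) or explicit input paths
#' (`responses`, `items`, plus optional `prescriptions`/`class_map` and
#' `scales`) must be given. The single global `seed` fans out to per-stage
#' seeds by fixed offsets, so every stage is individually reproducible.
#'
#' @param out_dir Output directory.
#' @param preset Synthetic scenario name (see [scenario()]), or `NULL`.
#' @param n Subjects to simulate when `preset` is set.
#' @param responses,items,prescriptions,scales Input file paths when
#'   `preset` is `NULL`.
#' @param class_map Drug -> class map (named vector or 2-column data frame)
#'   for `prescriptions`; defaults to [synthetic_class_map()].
#' @param k_grid k-means model sizes to sweep.
#' @param resolution_grid Louvain resolutions to sweep.
#' @param k_nn,p Similarity-graph parameters.
#' @param beta_threshold,lasso_penalty Feature-importance parameters.
#' @param min_labeled,rank_threshold Recommender parameters.
#' @param seed Global integer seed.
#' @param characterize,recommend Stage toggles.
#' @return A `transdx_runcfg` list.
#' @export
pipeline_config <- function(out_dir,
                            preset = "ukbb-like", n = 5000,
                            responses = NULL, items = NULL,
                            prescriptions = NULL, scales = NULL,
                            class_map = NULL,
                            k_grid = 2:8,
                            resolution_grid = c(0.5, 1, 2),
                            k_nn = 50, p = 2,
                            beta_threshold = 0.2, lasso_penalty = NULL,
                            min_labeled = 20, rank_threshold = 3,
                            seed = 1,
                            characterize = TRUE, recommend = TRUE) {
  if (is.null(preset) && (is.null(responses) || is.null(items))) {
    abort("either `preset` or `responses` + `items` paths are required")
  }
  structure(
    list(
      out_dir = out_dir, preset = preset, n = n,
      responses = responses, items = items,
      prescriptions = prescriptions, scales = scales,
      class_map = class_map,
      k_grid = as.integer(k_grid),
      resolution_grid = as.numeric(resolution_grid),
      k_nn = as.integer(k_nn), p = as.numeric(p),
      beta_threshold = as.numeric(beta_threshold),
      lasso_penalty = lasso_penalty,
      min_labeled = as.integer(min_labeled),
      rank_threshold = as.integer(rank_threshold),
      seed = as.integer(seed),
      characterize = isTRUE(characterize), recommend = isTRUE(recommend)
    ),
    class = "transdx_runcfg"
  )
}

#' Run the full profiling and recommendation pipeline
#'
#' Executes simulate (when a preset is configured) -> load/validate ->
#' encode/standardize -> score-based diagnosis + source comparison ->
#' k-means (silhouette-selected k) and Louvain (resolution sweep) ->
#' characterization -> both recommendation engines on the labeled subjects
#' -> evaluation. Every artifact is written under `cfg$out_dir` with a
#' schema header; the run report (JSON) aggregates quality metrics and a
#' per-stage log with output checksums; the resolved configuration is
#' written next to the outputs. Reruns with an identical configuration are
#' byte-identical. A stage failure aborts with the stage named; artifacts
#' already written are retained.
#'
#' @param cfg A `transdx_runcfg` from [pipeline_config()], or the path to a
#'   YAML file of its fields.
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    cfg <- do.call(pipeline_config, yaml::read_yaml(cfg))
  }
  stopifnot(inherits(cfg, "transdx_runcfg"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  written <- function(paths) {
    sums <- tools::md5sum(unlist(paths))
    lapply(names(sums), function(p) list(file = basename(p),
                                         md5 = unname(sums[[p]])))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }
  report <- list(schema = SCHEMA_VERSION, seed = cfg$seed)

  # -- simulate / load ------------------------------------------------------
  truth <- NULL
  stage("simulate", {
    if (!is.null(cfg$preset)) {
      syn <- scenario(cfg$preset, n = cfg$n, seed = cfg$seed)
      gen <- generate_cohort(syn)
      truth <- gen$truth
      input_dir <- file.path(cfg$out_dir, "inputs")
      write_cohort(gen$cohort, input_dir)
      scales_tbl <- generate_scale_scores(truth, syn)
      write_table_auto(scales_tbl, file.path(input_dir, "scales.tsv"))
      rx_gen <- generate_prescriptions(truth, syn)
      write_prescriptions(rx_gen, file.path(input_dir, "prescriptions.tsv"))
      cfg$responses <- file.path(input_dir, "responses.tsv")
      cfg$items <- file.path(input_dir, "items.tsv")
      cfg$scales <- file.path(input_dir, "scales.tsv")
      cfg$prescriptions <- file.path(input_dir, "prescriptions.tsv")
      cfg$class_map <- NULL
      log[["simulate"]] <- written(list(
        cfg$responses, cfg$items, cfg$scales, cfg$prescriptions))
    }
  })

  ch <- NULL
  stage("load", {
    ch <- load_cohort(cfg$responses, cfg$items)
  })
  rx <- NULL
  if (!is.null(cfg$prescriptions)) {
    stage("load", {
      rx <- load_prescriptions(cfg$prescriptions,
                                cfg$class_map %||% synthetic_class_map())
    })
  }

  # -- preprocess -----------------------------------------------------------
  fm <- NULL
  stage("preprocess", {
    fm <- standardize(encode_features(ch))
  })
  report$n_subjects <- nrow(fm$values)
  report$n_features <- ncol(fm$values)

  # -- diagnosis ------------------------------------------------------------
  dx <- NULL
  if (!is.null(cfg$scales)) {
    stage("diagnosis", {
      scores <- read_table_auto(cfg$scales)
      dx <- apply_score_diagnosis(scores)
      # noisy-recall surrogate for a second (self-reported) source
      dx_self <- perturb_diagnoses(dx, flip_prob = 0.15,
                                   seed = cfg$seed + 3L)
      cmp <- compare_diagnoses(dx_self, dx)
      report$diagnosis_inconsistency_rate <- cmp$inconsistency_rate
      write_table_auto(cmp$confusion,
                       file.path(cfg$out_dir, "diagnosis_confusion.csv"))
      log[["diagnosis"]] <- written(list(
        file.path(cfg$out_dir, "diagnosis_confusion.csv")))
    })
  }

  # -- profiling ------------------------------------------------------------
  km <- lv <- g <- NULL
  stage("profiling", {
    sel <- select_k_by_silhouette(fm, cfg$k_grid, seed = cfg$seed + 10L)
    km <- sel$assignment
    write_table_auto(sel$sweep, file.path(cfg$out_dir, "kmeans_sweep.csv"))
    g <- build_knn_graph(fm, k_nn = cfg$k_nn, p = cfg$p)
    swp <- sweep_resolution(g, fm, cfg$resolution_grid,
                            seed = cfg$seed + 11L)
    lv <- swp$best
    write_table_auto(swp$sweep, file.path(cfg$out_dir, "louvain_sweep.csv"))
    write_assignment(km, file.path(cfg$out_dir, "assignment_kmeans.tsv"))
    write_assignment(lv, file.path(cfg$out_dir, "assignment_louvain.tsv"))
    report$kmeans <- list(k = sel$best_k,
                           silhouette = km$quality$silhouette)
    report$louvain <- list(resolution = lv$params$resolution,
                            n_communities = n_clusters(lv),
                            modularity = lv$quality$modularity,
                            silhouette = lv$quality$silhouette)
    if (!is.null(truth) && requireNamespace("mclust", quietly = TRUE)) {
      tg <- truth$groups$group[match(km$assignments$subject_id,
                                     truth$groups$subject_id)]
      report$kmeans$ari <- mclust::adjustedRandIndex(
        km$assignments$cluster, tg)
      report$louvain$ari <- mclust::adjustedRandIndex(
        lv$assignments$cluster, tg)
    }
    log[["profiling"]] <- written(list(
      file.path(cfg$out_dir, "kmeans_sweep.csv"),
      file.path(cfg$out_dir, "louvain_sweep.csv"),
      file.path(cfg$out_dir, "assignment_kmeans.tsv"),
      file.path(cfg$out_dir, "assignment_louvain.tsv")))
  })

  # -- characterization -----------------------------------------------------
  if (cfg$characterize) {
    stage("characterize", {
      paths <- list()
      if (!is.null(dx)) {
        flows <- diagnosis_composition(km, dx)
        paths$flows <- file.path(cfg$out_dir, "sankey_flows.csv")
        write_table_auto(flows, paths$flows)
      }
      overlap <- diagnosis_composition(km, lv)
      paths$overlap <- file.path(cfg$out_dir, "method_overlap.csv")
      write_table_auto(overlap, paths$overlap)
      imp <- cluster_feature_importance(
        fm, km, beta_threshold = cfg$beta_threshold,
        penalty = cfg$lasso_penalty, seed = cfg$seed + 20L)
      paths$importance <- file.path(cfg$out_dir, "feature_importance.csv")
      write_table_auto(imp, paths$importance)
      cs <- category_index_scores(ch, km)
      paths$scores <- file.path(cfg$out_dir, "category_scores.csv")
      write_table_auto(cs$cluster_summary, paths$scores)
      report$n_important_features <- nrow(imp)
      log[["characterize"]] <- written(paths)
    })
  }

  # -- recommendation -------------------------------------------------------
  if (cfg$recommend && !is.null(rx)) {
    stage("recommend", {
      rates <- cluster_prescription_rate(km, rx)
      probs <- cluster_class_probability(km, rx)
      paths <- list(
        rates = file.path(cfg$out_dir, "cluster_prescription_rates.csv"),
        probs = file.path(cfg$out_dir, "cluster_class_probabilities.csv"),
        cluster_recs = file.path(cfg$out_dir, "recommendations_cluster.tsv"),
        network_recs = file.path(cfg$out_dir, "recommendations_network.tsv"),
        eval = file.path(cfg$out_dir, "evaluation.json")
      )
      write_table_auto(rates, paths$rates)
      write_table_auto(probs, paths$probs)
      labeled <- intersect(rx$subjects, fm$subject_ids)
      crec <- cluster_based_recommend(km, probs, subjects = labeled,
                                      rank_threshold = cfg$rank_threshold)
      nrec <- network_based_recommend(g, rx, subjects = labeled,
                                      min_labeled = cfg$min_labeled,
                                      rank_threshold = cfg$rank_threshold)
      write_table_auto(crec, paths$cluster_recs)
      write_table_auto(nrec, paths$network_recs)
      ev_c <- evaluate_recommendations(crec, rx, km)
      ev_n <- evaluate_recommendations(nrec, rx, km)
      report$overall_prescription_rate <- attr(rates, "overall_rate")
      report$cluster_engine <- glance(ev_c)
      report$network_engine <- glance(ev_n)
      report$network_size_distribution <- ev_n$size_distribution
      jsonlite::write_json(
        list(cluster = glance(ev_c), network = glance(ev_n),
             network_size_distribution = ev_n$size_distribution),
        paths$eval, auto_unbox = TRUE, digits = NA, pretty = TRUE,
        dataframe = "rows")
      log[["recommend"]] <- written(paths)
    })
  }

  # -- report ---------------------------------------------------------------
  report$stages <- log
  resolved <- cfg
  class(resolved) <- NULL
  yaml::write_yaml(resolved[!vapply(resolved, is.null, TRUE)],
                   file.path(cfg$out_dir, "config_resolved.yaml"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Flip diagnosis memberships at random (noisy-label surrogate)
#'
#' Produces a second diagnosis source by independently flipping each
#' subject's membership in each observed diagnosis with probability
#' `flip_prob` — a simple model of imperfect self-report recall, used by the
#' pipeline to exercise the source-comparison stage on synthetic cohorts.
#'
#' @param labels A `transdx_diagnoses`.
#' @param flip_prob Per-diagnosis flip probability.
#' @param seed Integer seed.
#' @return A `transdx_diagnoses` with source `"self_reported"`.
#' @export
perturb_diagnoses <- function(labels, flip_prob = 0.15, seed = 1) {
  vocab <- sort(unique(unlist(labels$diagnoses)))
  with_seed(seed, {
    flipped <- lapply(labels$diagnoses, function(d) {
      flip <- vocab[stats::runif(length(vocab)) < flip_prob]
      union(setdiff(d, flip), setdiff(flip, d))
    })
    diagnosis_labels(labels$subject_id, flipped, source = "self_reported")
  })
}
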