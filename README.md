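# transdx

Transdiagnostic symptom profiling and drug-class recommendation for
mental-health questionnaire cohorts.

## What it does, and for whom

Mental-health questionnaire cohorts — a hundred-plus mixed-type items per
subject organized in eight symptom categories (A–H), a small fraction of
subjects with linked psychotropic prescription histories, and diagnosis
labels from imperfectly agreeing sources — invite a *transdiagnostic*
analysis: characterize each subject by their full symptom profile rather
than a diagnostic label, find intrinsic subgroups, and read treatment
signals off similar subjects. `transdx` is an R toolkit for exactly that
workflow, aimed at psychiatric epidemiologists and clinical-informatics
teams prototyping decision-support pipelines on questionnaire data.

The pipeline:

1. **Encode**: one-hot categorical items (missing-value indicators
   dropped), single numeric columns for binary/ordinal/continuous items,
   age and sex appended; complete-case filtering; standard scaling
   (per-column z-scores, population SD).
2. **Profile**: k-means (Lloyd, Euclidean, multi-restart) with the number
   of clusters k chosen by mean silhouette
   s(i) = (b(i) − a(i)) / max(a(i), b(i)); and, in parallel, Louvain
   community detection (greedy modularity
   Q = Σ_c [e_c/m − (d_c/2m)²] maximization) on a k-nearest-neighbour
   graph (union-symmetrized, Minkowski p = 2, default k_nn = 100), with
   the resolution chosen by feature-space silhouette.
3. **Characterize**: diagnosis-to-cluster flow tables (Sankey input),
   per-cluster L1-penalized logistic regression of membership with
   features reported above β > 0.2, and min–max category index scores.
4. **Recommend**: two engines sharing competition ranking (ties share a
   rank, classes at rank ≤ 3 recommended, zero-count classes never):
   *cluster-based* — P(class | cluster) among prescription-labeled
   members; *network-based* — the subject's graph neighbourhood grows
   breadth-first, whole ring by whole ring, until it holds ≥ 20 labeled
   neighbours (the quota is configurable), and classes are ranked by
   neighbourhood prescription counts.
5. **Diagnose & compare**: scale-threshold rules (depression: HAMD ≥ 7;
   anxiety: HAMA ≥ 10 or PDSS ≥ 8; bipolar: MDQ ≥ 7 or HCL-32 ≥ 12) and
   per-subject agreement between diagnosis sources.

Real cohorts of this shape are access-controlled, so the package ships a
synthetic generator (`scenario("separable-4" | "ukbb-like" | "flat-null")`)
with known latent groups, group-conditional prescription probabilities and
scale scores; every pipeline stage is exercised and validated against that
ground truth. See `vignettes/transdiagnostic-profiling.Rmd` for the model
details, parameter defaults and design decisions.

## Worked example

```r
library(transdx)

cfg <- pipeline_config(out_dir = "run", preset = "separable-4",
                       n = 2000, seed = 7)
report <- run_pipeline(cfg)

str(report$kmeans)
#> List of 3
#>  $ k         : int 4
#>  $ silhouette: num 0.32
#>  $ ari       : num 1
str(report$louvain)
#> List of 5
#>  $ resolution   : num 0.5
#>  $ n_communities: int 4
#>  $ modularity   : num 0.749
#>  $ silhouette   : num 0.32
#>  $ ari          : num 1
report$overall_prescription_rate
#> [1] 0.188
str(report$network_engine)
#>  $ n_subjects        : int 376
#>  $ hit_rate          : num 0.987
#>  $ exact_rate        : num 0.0346
#>  $ mean_n_recommended: num 3.02
```

Reading: on a 2,000-subject synthetic cohort with four planted symptom
groups, silhouette selection picks k = 4 and both k-means and Louvain
recover the planted grouping perfectly (adjusted Rand index 1); 18.8% of
subjects carry prescriptions, and for those labeled subjects the network
engine's recommended class set contains an actually prescribed class 98.7%
of the time (lists average ~3 classes under the default rank-3 cutoff, so
exact set matches are rare). Artifacts — simulated inputs, assignments,
sweep tables, flow/importance/score tables, recommendation tables, an
evaluation JSON and a checksummed stage log — land under `run/`.

Individual stages compose with the pipe as plain functions, e.g.

```r
gen <- generate_cohort(scenario("separable-4", n = 2000, seed = 7))
fm  <- gen$cohort |> encode_features() |> standardize()
km  <- fit_kmeans(fm, k = 4, seed = 7)
g   <- build_knn_graph(fm, k_nn = 50)
rx  <- generate_prescriptions(gen$truth, scenario("separable-4", n = 2000, seed = 7))
network_based_recommend(g, rx, min_labeled = 20) |>
  evaluate_recommendations(rx, km) |>
  glance()
```

A thin command-line front-end lives at `inst/scripts/transdx.R`
(`simulate` and `run` subcommands).

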