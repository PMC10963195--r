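#' Run the full thyroid-signature analysis pipeline
#'
#' Chains the analysis stages end to end: eligibility accounting,
#' calculated homeostasis parameters, endotype classification, TSH-by-FT4
#' clustering with silhouette-selected k and output labelling, survivor
#' comparisons, ROC-derived survival cutoffs, Kaplan-Meier / log-rank
#' analyses (by cutoff and by cluster), the Cox modelling stack and the
#' composite complication endpoint. Either an input CSV or the synthetic
#' generator supplies the cohort. All result tables are returned; when
#' `output_dir` is given they are also written as CSV/JSON artifacts
#' together with the resolved configuration.
#'
#' @param input Path to a cohort CSV (see [read_cohort()]); ignored when
#'   `simulate = TRUE`.
#' @param simulate Generate the cohort with [simulate_cohort()] instead of
#'   reading a file.
#' @param seed Seed for the generator and all bootstrap stages.
#' @param stages Character vector of stages to run, a subset of
#'   `c("indices", "endotype", "cluster", "comparisons", "cutoffs",
#'   "survival", "cox", "composite")`; later stages that depend on skipped
#'   ones are skipped too.
#' @param constants A [spina_constants()] object.
#' @param ranges A [reference_ranges()] object.
#' @param k_range Candidate k for the cluster stage.
#' @param rom_reps Bootstrap replicates for ratio-of-medians CIs.
#' @param output_dir Optional directory for artifacts.
#' @param unit_dialect Passed to [read_cohort()].
#' @return A list of class `thyro_pipeline` with the cohort (augmented with
#'   indices/endotype/cluster columns), `flow`, `clusters`, `comparisons`,
#'   `endotype_freq`, `cutoffs`, `km_cluster`, `km_cutoffs`, `cox`,
#'   `composite` and the resolved `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(simulate = TRUE, seed = 7, rom_reps = 200)
#' res$flow
#' }
run_pipeline <- function(input = NULL, simulate = is.null(input), seed = 1L,
                         stages = c("indices", "endotype", "cluster",
                                    "comparisons", "cutoffs", "survival",
                                    "cox", "composite"),
                         constants = spina_constants(),
                         ranges = reference_ranges(),
                         k_range = 2:6, rom_reps = 2000,
                         output_dir = NULL,
                         unit_dialect = "SI_pmol") {
  cohort <- if (simulate) {
    simulate_cohort(seed = seed)
  } else {
    read_cohort(input, unit_dialect = unit_dialect)
  }
  out <- list(config = list(seed = seed, stages = stages, k_range = k_range,
                            rom_reps = rom_reps,
                            provenance = config_provenance(constants, ranges)))
  out$flow <- cohort_flow(cohort)

  if ("indices" %in% stages) {
    cohort <- add_thyroid_indices(cohort, constants = constants)
  }
  if ("endotype" %in% stages) {
    cohort <- add_endotype(cohort, ranges = ranges)
    out$endotype_freq <- endotype_frequencies(cohort, by = "died")
  }
  if ("cluster" %in% stages && "indices" %in% stages) {
    clusters <- cluster_thyroid(cohort, k_range = k_range, seed = seed)
    if (clusters$model$k == 3) clusters <- label_clusters(clusters, cohort)
    cohort <- add_cluster(cohort, clusters)
    out$clusters <- clusters
  }
  if ("comparisons" %in% stages) {
    vars <- intersect(c("age", "tsh", "ft4", "ft3", "spina_gt", "spina_gd",
                        "jti", "ttsi", "tfqi", "creatinine", "initial_ef",
                        "hypertension", "diabetes", "hypercholesterolemia",
                        "smoking", "atrial_fibrillation", "malignancy",
                        "neurological", "psychiatric", "cad"),
                      names(cohort))
    out$comparisons <- compare_groups(cohort, "died", vars,
                                      rom_reps = rom_reps, seed = seed)
  }
  if ("cutoffs" %in% stages && "indices" %in% stages) {
    out$cutoffs <- survival_cutoffs(cohort)
  }
  if ("survival" %in% stages) {
    if (!is.null(out$clusters) && "cluster_label" %in% names(cohort)) {
      out$km_cluster <- kaplan_meier(cohort, "cluster_label")
    }
    if (!is.null(out$cutoffs) && nrow(out$cutoffs) > 0) {
      out$km_cutoffs <- purrr::map(stats::setNames(out$cutoffs$marker,
                                                   out$cutoffs$marker),
        function(mk) {
          cut <- out$cutoffs$cutoff_phi[out$cutoffs$marker == mk]
          strat <- dplyr::mutate(cohort,
            above_cutoff = .data[[mk]] >= cut)
          kaplan_meier(strat, "above_cutoff")
        })
    }
  }
  if ("cox" %in% stages) {
    out$cox <- cox_models(cohort)
  }
  if ("composite" %in% stages) {
    comp <- composite_endpoint(cohort, rom_reps = rom_reps, seed = seed)
    cohort <- comp$cohort
    out$composite <- comp$comparisons
  }
  out$cohort <- cohort

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort_annotated.csv"))
    write_flow_json(cohort, file.path(output_dir, "flow.json"))
    jsonlite::write_json(out$config, file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_tbl <- function(tbl, name) {
      if (!is.null(tbl) && nrow(tbl) > 0) {
        readr::write_csv(tbl, file.path(output_dir, name))
      }
    }
    write_tbl(out$comparisons, "survivor_comparisons.csv")
    write_tbl(out$endotype_freq, "endotype_frequencies.csv")
    write_tbl(out$cutoffs, "survival_cutoffs.csv")
    if (!is.null(out$clusters)) {
      write_tbl(tidy(out$clusters), "cluster_medoids.csv")
      write_tbl(out$clusters$profile, "silhouette_profile.csv")
    }
    if (!is.null(out$km_cluster)) write_tbl(tidy(out$km_cluster), "km_clusters.csv")
    if (!is.null(out$cox)) write_tbl(tidy(out$cox), "cox_models.csv")
    write_tbl(out$composite, "composite_endpoint.csv")
  }
  structure(out, class = "thyro_pipeline")
}

#' @export
print.thyro_pipeline <- function(x, ...) {
  cat("thyroid-signature pipeline run\n")
  print(x$flow)
  if (!is.null(x$clusters)) {
    cat("selected k =", x$clusters$model$k, "; labels:",
        paste(x$clusters$labels, collapse = "/"), "\n")
  }
  if (!is.null(x$km_cluster) && !is.na(x$km_cluster$logrank_p)) {
    cat(sprintf("log-rank across clusters: p = %.3g\n", x$km_cluster$logrank_p))
  }
  invisible(x)
}
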