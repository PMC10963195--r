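#' Cluster a cohort in the TSH-by-FT4 plane
#'
#' Restricts the cohort to records with both TSH and FT4, z-standardizes the
#' two axes (so the Euclidean distance is not dominated by FT4's larger
#' numeric range), runs PAM over a range of candidate k and keeps the model
#' with the highest average silhouette width. Medoids are reported back in
#' the original concentration units.
#'
#' @param cohort A cohort tibble.
#' @param k_range Candidate numbers of clusters (default 2:8).
#' @param standardize z-standardize each axis before distance computation
#'   (default `TRUE`; raw concentrations, not logs).
#' @param seed Recorded for provenance; clustering itself is deterministic.
#' @return An object of class `thyro_clusters`: list with `model` (the
#'   selected [pam_fit()] object in standardized space), `assignment`
#'   (tibble `patient_id`, `cluster`), `medoids` (tibble `cluster`, `tsh`,
#'   `ft4` in original units), `profile` (average silhouette per k),
#'   `labels` (all `"unlabelled"` until [label_clusters()] runs) and the
#'   eligible data.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_total = 120, n_panel = 100, n_full_panel = 70,
#'                           seed = 3)
#' cl <- cluster_thyroid(cohort, k_range = 2:4)
#' cl$medoids
cluster_thyroid <- function(cohort, k_range = 2:8, standardize = TRUE,
                            seed = NULL) {
  eligible <- cohort[!is.na(cohort$tsh) & !is.na(cohort$ft4), , drop = FALSE]
  if (nrow(eligible) < max(k_range) + 1) {
    stop("too few complete TSH+FT4 records (", nrow(eligible),
         ") for k_range up to ", max(k_range), call. = FALSE)
  }
  raw <- cbind(tsh = eligible$tsh, ft4 = eligible$ft4)
  feats <- if (standardize) scale(raw) else raw
  model <- select_k(feats, k_range = k_range, seed = seed)
  medoids <- tibble::tibble(
    cluster = seq_len(model$k),
    tsh = raw[model$medoid_idx, "tsh"],
    ft4 = raw[model$medoid_idx, "ft4"]
  )
  structure(
    list(
      model = model,
      assignment = tibble::tibble(patient_id = eligible$patient_id,
                                  cluster = model$assignment),
      medoids = medoids,
      profile = model$profile,
      labels = rep("unlabelled", model$k),
      label_diagnostics = NULL,
      data = eligible,
      standardize = standardize,
      seed = seed
    ),
    class = "thyro_clusters"
  )
}

#' Label clusters by their position relative to the median secretory capacity
#'
#' For a three-cluster solution the clusters are named after their thyroid
#' output relative to the cohort-median SPINA-GT: the cluster whose members
#' lie predominantly below the median GT and whose medoid TSH is highest is
#' the low-output cluster (TSLT); of the remaining two, the cluster whose
#' members lie on or above the median GT with the highest medoid FT4 is the
#' high-output cluster (TSHT); the remaining cluster is the normal-output
#' cluster (TSNT). The fraction of members on the "wrong" side of the
#' median GT is reported per labelled cluster as a diagnostic. For k != 3
#' all clusters stay unlabelled with a notice.
#'
#' @param clusters A `thyro_clusters` object.
#' @param cohort A cohort tibble carrying `spina_gt` (see
#'   [add_thyroid_indices()]); must cover the clustered patient ids.
#' @return The `thyro_clusters` object with `labels` set
#'   (`c("TSLT", "TSHT", "TSNT")` indexed by cluster) and
#'   `label_diagnostics` (tibble with `cluster`, `label`, `n`,
#'   `frac_below_median_gt`, `violation_frac`).
#' @export
label_clusters <- function(clusters, cohort) {
  stopifnot(inherits(clusters, "thyro_clusters"))
  if (!"spina_gt" %in% names(cohort)) {
    stop("cohort must carry spina_gt; run add_thyroid_indices() first",
         call. = FALSE)
  }
  if (clusters$model$k != 3) {
    message("cluster labels are defined for k = 3 only; leaving ",
            clusters$model$k, " clusters unlabelled")
    clusters$labels <- rep("unlabelled", clusters$model$k)
    return(clusters)
  }
  gt <- cohort$spina_gt[match(clusters$assignment$patient_id, cohort$patient_id)]
  gt_median <- stats::median(gt, na.rm = TRUE)
  assignment <- clusters$assignment$cluster
  frac_below <- vapply(1:3, function(cl) {
    g <- gt[assignment == cl]
    mean(g < gt_median, na.rm = TRUE)
  }, numeric(1))
  sizes <- tabulate(assignment, 3)

  labels <- rep(NA_character_, 3)
  # low-output cluster: predominantly below-median GT, highest medoid TSH
  tslt <- order(-clusters$medoids$tsh)[1]
  labels[tslt] <- "TSLT"
  rest <- setdiff(1:3, tslt)
  tsht <- rest[order(-clusters$medoids$ft4[rest])[1]]
  labels[tsht] <- "TSHT"
  labels[setdiff(rest, tsht)] <- "TSNT"

  violation <- ifelse(labels == "TSLT", 1 - frac_below,
                      ifelse(labels == "TSHT", frac_below, NA_real_))
  clusters$labels <- labels
  clusters$label_diagnostics <- tibble::tibble(
    cluster = 1:3, label = labels, n = sizes,
    frac_below_median_gt = frac_below, violation_frac = violation
  )
  clusters
}

#' Append cluster assignment and label to a cohort
#'
#' @param cohort A cohort tibble.
#' @param clusters A `thyro_clusters` object (after [label_clusters()] if
#'   labels are wanted).
#' @return The cohort with `cluster` (integer, `NA` for records not in the
#'   cluster analysis) and `cluster_label` columns.
#' @export
add_cluster <- function(cohort, clusters) {
  idx <- match(cohort$patient_id, clusters$assignment$patient_id)
  cl <- clusters$assignment$cluster[idx]
  dplyr::mutate(cohort,
                cluster = cl,
                cluster_label = ifelse(is.na(cl), NA_character_,
                                       clusters$labels[cl]))
}

#' Concordance of PAM assignment with agglomerative clustering
#'
#' A numerical plausibility check standing in for visual dendrogram
#' inspection: cuts an average-linkage hierarchical tree at the same k and
#' reports the adjusted Rand index against the PAM assignment.
#'
#' @param clusters A `thyro_clusters` object.
#' @return A list with `k` and `adjusted_rand`.
#' @export
hclust_concordance <- function(clusters) {
  raw <- cbind(clusters$data$tsh, clusters$data$ft4)
  feats <- if (isTRUE(clusters$standardize)) scale(raw) else raw
  hc <- stats::hclust(stats::dist(feats), method = "average")
  hc_assign <- stats::cutree(hc, k = clusters$model$k)
  list(k = clusters$model$k,
       adjusted_rand = adjusted_rand_index(clusters$model$assignment, hc_assign))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.thyro_clusters <- function(x, ...) {
  cat("thyroid-signature clusters: k =", x$model$k,
      " avg silhouette =", round(x$model$avg_silhouette, 3), "\n")
  print(dplyr::mutate(x$medoids, label = x$labels,
                      n = tabulate(x$model$assignment, x$model$k)))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of the TSH-by-FT4 clusters with medoids marked
#'
#' @param object A `thyro_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thyro_clusters
#' @export
autoplot.thyro_clusters <- function(object, ...) {
  df <- dplyr::mutate(object$data,
                      cluster = factor(object$model$assignment,
                                       labels = object$labels))
  med <- dplyr::mutate(object$medoids, label = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tsh, y = .data$ft4,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = med, ggplot2::aes(colour = .data$label),
                        shape = 4, size = 5, stroke = 2, show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "TSH (mIU/L, log scale)", y = "FT4 (pmol/L)",
                  colour = "cluster",
                  title = "TSH-by-FT4 clusters (X = medoid)") +
    ggplot2::theme_minimal()
}
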