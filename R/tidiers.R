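#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn pam_fit Per-cluster summary: cluster index, size, medoid row.
#' @param x A `thyro_pam` object.
#' @param ... Unused.
#' @method tidy thyro_pam
#' @export
tidy.thyro_pam <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = tabulate(x$assignment, x$k),
    medoid_row = x$medoid_idx
  )
}

#' @describeIn pam_fit One-row model summary: k, cost, iterations, average
#'   silhouette width where computed.
#' @method glance thyro_pam
#' @export
glance.thyro_pam <- function(x, ...) {
  tibble::tibble(
    k = x$k, cost = x$cost, iterations = x$iterations,
    avg_silhouette = x$avg_silhouette %||% NA_real_
  )
}

#' @describeIn cluster_thyroid Medoids in original units with labels and
#'   cluster sizes.
#' @param x A `thyro_clusters` object.
#' @param ... Unused.
#' @method tidy thyro_clusters
#' @export
tidy.thyro_clusters <- function(x, ...) {
  dplyr::mutate(x$medoids, label = x$labels,
                size = tabulate(x$model$assignment, x$model$k))
}

#' @describeIn cluster_thyroid One-row summary: selected k, average
#'   silhouette width, number of records clustered.
#' @method glance thyro_clusters
#' @export
glance.thyro_clusters <- function(x, ...) {
  tibble::tibble(k = x$model$k, avg_silhouette = x$model$avg_silhouette,
                 n = nrow(x$data))
}

#' @describeIn kaplan_meier Tidy step-function table.
#' @param x A `thyro_km` object.
#' @param ... Unused.
#' @method tidy thyro_km
#' @export
tidy.thyro_km <- function(x, ...) x$steps

#' @describeIn kaplan_meier One-row summary with the log-rank comparison.
#' @method glance thyro_km
#' @export
glance.thyro_km <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = sum(x$steps$n_event),
                 logrank_chisq = x$logrank_chisq, logrank_df = x$logrank_df,
                 logrank_p = x$logrank_p)
}

#' @describeIn cox_models All model coefficient tables stacked, with a
#'   `model` column (`"univariable"`, `"multivariable"`, `"frailty"`).
#' @param x A `thyro_cox` object.
#' @param ... Unused.
#' @method tidy thyro_cox
#' @export
tidy.thyro_cox <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$univariable, model = "univariable"),
    if (nrow(x$multivariable) > 0) dplyr::mutate(x$multivariable, model = "multivariable"),
    if (nrow(x$frailty) > 0) dplyr::mutate(x$frailty, model = "frailty")
  )
}

#' @describeIn cox_models One-row summary of the stepwise selection.
#' @method glance thyro_cox
#' @export
glance.thyro_cox <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$univariable), n_entrants = length(x$entrants),
    n_minimal = nrow(x$multivariable), n_multivariable = x$n_multivariable,
    entry_p = x$entry_p, stay_p = x$stay_p
  )
}

#' @describeIn optimal_cutoffs Two-row tibble: one row per cutoff statistic.
#' @param x A `thyro_cutoff` object.
#' @param ... Unused.
#' @method tidy thyro_cutoff
#' @export
tidy.thyro_cutoff <- function(x, ...) {
  tibble::tibble(
    statistic = c("phi", "youden"),
    cutoff = c(x$cutoff_phi, x$cutoff_youden),
    value = c(x$phi, x$youden),
    direction = c(x$direction_phi, x$direction_youden)
  )
}
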