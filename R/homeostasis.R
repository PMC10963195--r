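#' Thyroid's secretory capacity (SPINA-GT)
#'
#' Estimates the maximal stimulated thyroxine output of the thyroid gland
#' from a simultaneous TSH and FT4 measurement, by inverting the
#' steady-state feedback model of the pituitary-thyroid axis:
#'
#' \deqn{\hat G_T = \frac{\beta_T (D_T + TSH)(1 + K_{41} TBG + K_{42} TTR)\,
#'   FT4}{\alpha_T \, TSH}}
#'
#' with FT4 in molar units; the result is returned in pmol/s. GT is strictly
#' increasing in FT4 and strictly decreasing in TSH (a high hormone output
#' maintained despite little thyrotropic stimulation implies a large gland
#' capacity). Undefined inputs (missing, or TSH = 0) yield `NA` rather than
#' an error, so the function can run over a whole admission panel.
#'
#' @param tsh TSH in mIU/L (vector).
#' @param ft4 Free T4 in pmol/L (vector).
#' @param constants A [spina_constants()] object.
#' @return Secretory capacity in pmol/s (vector, `NA` where undefined).
#' @export
#' @examples
#' spina_gt(1.0, 14.1)  # ~4.0 pmol/s
spina_gt <- function(tsh, ft4, constants = spina_constants()) {
  k <- constants
  ft4_molar <- ft4 * 1e-12
  binding <- 1 + k$K41 * k$TBG + k$K42 * k$TTR_sub
  gt <- k$beta_T * (k$D_T + tsh) * binding * ft4_molar / (k$alpha_T * tsh)
  gt[!is.na(tsh) & tsh <= 0] <- NA_real_
  gt[!is.na(ft4) & ft4 < 0] <- NA_real_
  gt * 1e12  # mol/s -> pmol/s
}

#' Sum activity of peripheral deiodinases (SPINA-GD)
#'
#' Estimates the total T4-to-T3 step-up conversion capacity from a
#' simultaneous FT4 and FT3 measurement:
#'
#' \deqn{\hat G_D = \frac{\beta_{31}(K_{M1} + FT4)(1 + K_{30} TBG)\, FT3}
#'   {\alpha_{31}\, FT4}}
#'
#' with hormones in molar units; the result is returned in nmol/s. GD is
#' linear in FT3; since circulating FT4 is far below the deiodinase
#' Michaelis constant, GD falls with rising FT4 at fixed FT3 (the same T3
#' yield from more substrate implies less enzyme activity).
#'
#' @param ft3 Free T3 in pmol/L (vector).
#' @param ft4 Free T4 in pmol/L (vector).
#' @param constants A [spina_constants()] object.
#' @return Deiodinase activity in nmol/s (vector, `NA` where undefined).
#' @export
#' @examples
#' spina_gd(4.0, 14.1)  # ~27 nmol/s
spina_gd <- function(ft3, ft4, constants = spina_constants()) {
  k <- constants
  ft4_molar <- ft4 * 1e-12
  ft3_molar <- ft3 * 1e-12
  gd <- k$beta_31 * (k$K_M1 + ft4_molar) * (1 + k$K30 * k$TBG) * ft3_molar /
    (k$alpha_31 * ft4_molar)
  gd[!is.na(ft4) & ft4 <= 0] <- NA_real_
  gd[!is.na(ft3) & ft3 < 0] <- NA_real_
  gd * 1e9  # mol/s -> nmol/s
}

#' Jostel's TSH index (JTI)
#'
#' Logarithmic index of thyrotropic pituitary function that corrects the
#' observed TSH for the prevailing FT4 level:
#' \deqn{JTI = \ln(TSH) + 0.1345 \cdot FT4}
#' with FT4 in pmol/L. Low values indicate reduced central stimulation
#' (thyrotropic insufficiency or downward allostatic adaptation).
#'
#' @param tsh TSH in mIU/L (vector).
#' @param ft4 Free T4 in pmol/L (vector).
#' @return Dimensionless index (vector, `NA` where TSH is missing or 0).
#' @export
jostel_tsh_index <- function(tsh, ft4) {
  jti <- log(tsh) + 0.1345 * ft4
  jti[!is.na(tsh) & tsh <= 0] <- NA_real_
  jti
}

#' Thyrotroph thyroid hormone resistance index (TTSI)
#'
#' The TSH-FT4 product normalized to the assay's upper FT4 reference limit:
#' \deqn{TTSI = 100 \cdot TSH \cdot FT4 / FT4_{upper}}
#' Elevated values suggest reduced pituitary sensitivity to thyroid hormone.
#'
#' @param tsh TSH in mIU/L (vector), may be 0.
#' @param ft4 Free T4 in pmol/L (vector).
#' @param constants A [spina_constants()] object supplying `ft4_upper_ref`.
#' @return Dimensionless index (vector).
#' @export
ttsi <- function(tsh, ft4, constants = spina_constants()) {
  out <- 100 * tsh * ft4 / constants$ft4_upper_ref
  out[!is.na(tsh) & tsh < 0] <- NA_real_
  out
}

#' Thyroid feedback quantile-based index (TFQI)
#'
#' A distribution-based measure of the set point of the pituitary-thyroid
#' feedback: \deqn{TFQI = F_{FT4}(FT4) - (1 - F_{TSH}(TSH))} where the
#' \eqn{F} are cumulative distribution functions of a reference population.
#' Positive values indicate an FT4 quantile higher than the complementary
#' TSH quantile, i.e. reduced central sensitivity to thyroid hormone.
#' Values lie in \[-1, 1\] and average ~0 under the empirical reference.
#'
#' With `reference = "empirical"` (the default) the analysed cohort itself
#' is the reference and mid-rank quantiles `(rank - 0.5)/n` are used, which
#' makes the cohort mean of TFQI exactly 0 up to ties. With
#' `reference = "parametric"` a Gaussian reference on ln(TSH) and raw FT4 is
#' used, parameterized by `tsh_meanlog`/`tsh_sdlog` and `ft4_mean`/`ft4_sd`.
#'
#' @param tsh TSH in mIU/L (vector).
#' @param ft4 Free T4 in pmol/L (vector, same length).
#' @param reference `"empirical"` or `"parametric"`.
#' @param tsh_meanlog,tsh_sdlog,ft4_mean,ft4_sd Parameters of the parametric
#'   reference; ignored for the empirical reference.
#' @return Vector of TFQI values in \[-1, 1\]; `NA` where either input is
#'   missing.
#' @export
tfqi <- function(tsh, ft4, reference = c("empirical", "parametric"),
                 tsh_meanlog = NULL, tsh_sdlog = NULL,
                 ft4_mean = NULL, ft4_sd = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(tsh) == length(ft4))
  complete <- !is.na(tsh) & !is.na(ft4)
  out <- rep(NA_real_, length(tsh))
  if (reference == "empirical") {
    n <- sum(complete)
    if (n < 2) stop("empirical TFQI reference needs at least 2 complete pairs",
                    call. = FALSE)
    # mid-rank quantiles: F(x) = (rank - 0.5) / n, average ranks for ties
    f_ft4 <- (rank(ft4[complete], ties.method = "average") - 0.5) / n
    f_tsh <- (rank(tsh[complete], ties.method = "average") - 0.5) / n
    out[complete] <- f_ft4 - (1 - f_tsh)
  } else {
    if (is.null(tsh_meanlog) || is.null(tsh_sdlog) ||
        is.null(ft4_mean) || is.null(ft4_sd)) {
      stop("parametric TFQI reference needs tsh_meanlog, tsh_sdlog, ft4_mean, ft4_sd",
           call. = FALSE)
    }
    f_ft4 <- stats::pnorm(ft4[complete], ft4_mean, ft4_sd)
    f_tsh <- stats::pnorm(log(tsh[complete]), tsh_meanlog, tsh_sdlog)
    out[complete] <- f_ft4 - (1 - f_tsh)
  }
  out
}

#' Append calculated homeostasis parameters to a cohort
#'
#' Adds the five structure parameters as columns `spina_gt`, `spina_gd`,
#' `jti`, `ttsi` and `tfqi`. SPINA-GT is only calculated in subjects not on
#' levothyroxine substitution therapy, because exogenous thyroxine decouples
#' the measured FT4 from the gland's own output; records on levothyroxine
#' get `NA`. TFQI uses the records with a complete TSH+FT4 panel as its
#' empirical reference population.
#'
#' @param cohort A cohort tibble with columns `tsh`, `ft4`, `ft3`,
#'   `on_levothyroxine`.
#' @param constants A [spina_constants()] object.
#' @param tfqi_reference Passed to [tfqi()] (`"empirical"` default).
#' @param ... Further arguments passed to [tfqi()] for the parametric
#'   reference.
#' @return The cohort with five additional columns.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_total = 50, n_panel = 40, n_full_panel = 30,
#'                           seed = 1)
#' dplyr::select(add_thyroid_indices(cohort), patient_id, spina_gt:tfqi)
add_thyroid_indices <- function(cohort, constants = spina_constants(),
                                tfqi_reference = "empirical", ...) {
  on_lt <- cohort$on_levothyroxine
  gt <- spina_gt(cohort$tsh, cohort$ft4, constants)
  gt[!is.na(on_lt) & on_lt] <- NA_real_
  dplyr::mutate(
    cohort,
    spina_gt = gt,
    spina_gd = spina_gd(.data$ft3, .data$ft4, constants),
    jti = jostel_tsh_index(.data$tsh, .data$ft4),
    ttsi = ttsi(.data$tsh, .data$ft4, constants),
    tfqi = tfqi(.data$tsh, .data$ft4, reference = tfqi_reference, ...)
  )
}
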