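#' Cluster mixture parameters of the synthetic registry cohort
#'
#' Three-component structure in the (TSH, FT4) plane emulating the
#' registry: a low-output component (moderately high TSH, low-to-normal
#' FT4), a high-output component (low-to-normal TSH, elevated FT4) and a
#' normal-output component. Locations and spreads are log-normal, with
#' `meanlog = log(median)` and `sdlog` derived from the interquartile range
#' via the log-normal quartile identity `sdlog = log(q3/q1) / (2 z_{0.75})`.
#' Deiodinase activity (GD) is drawn per subject and inverted through the
#' SPINA-GD relation to produce FT3, so the generated panel embodies the
#' deiodinase interpretation of the low-T3 state. Ages and ejection
#' fractions are Gaussian per component (the high-output component is older
#' with lower EF); key covariate prevalences differ by component where the
#' registry reported them separately.
#'
#' @return A tibble with one row per mixture component.
#' @export
cluster_mixture_params <- function() {
  tibble::tibble(
    cluster = 1:3,
    label = c("TSLT", "TSHT", "TSNT"),
    weight = c(0.27, 0.12, 0.61),
    tsh_median = c(2.8, 0.9, 1.0),
    tsh_q1 = c(1.9, 0.4, 0.4),   # low-output TSH IQR lower bound repaired
    tsh_q3 = c(5.1, 1.7, 1.5),
    ft4_median = c(13.5, 24.3, 14.1),
    ft4_q1 = c(11.8, 22.2, 12.5),
    ft4_q3 = c(17.1, 28.6, 16.1),
    gd_median = c(22.4, 16.2, 25.6),
    gd_q1 = c(16.7, 12.7, 17.6),
    gd_q3 = c(29.8, 21.2, 30.5),
    age_mean = c(71.1, 76.7, 69.3),
    age_sd = c(11.1, 9.9, 13.3),
    ef_mean = c(45.2, 38.4, 44.5),
    ef_sd = c(12.5, 11.3, 13.6),
    p_atrial_fibrillation = c(0.17, 0.31, 0.15),
    p_malignancy = c(0.14, 0.14, 0.07),
    p_trigger_physical = c(0.31, 0.57, 0.31),
    p_female = c(0.91, 0.89, 0.88)
  )
}

sdlog_from_iqr <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Generate a registry-like synthetic cohort
#'
#' Draws `n_total` admissions from the three-component TSH-by-FT4 mixture
#' of [cluster_mixture_params()], produces FT3 through the deiodinase
#' relation, assigns demographics, comorbidities, triggers and in-hospital
#' complications at registry-matched prevalences, and simulates all-cause
#' fatality with an exponential survival model whose hazard depends on the
#' mixture component (the low-output component carries the best prognosis)
#' and on FT3, ejection fraction, atrial fibrillation and malignancy.
#' Follow-up is right-censored uniformly over the follow-up window. Panel
#' missingness is applied completely at random so that exactly `n_panel`
#' records have both TSH and FT4, of which `n_full_panel` also have FT3;
#' outcome data are retained for `n_outcome` records.
#'
#' All randomness is governed by `seed`; the full configuration is echoed
#' into the `"generator_config"` attribute of the result, and the true
#' component of each record is kept in `true_cluster` for recovery
#' experiments.
#'
#' @param n_total Number of screened admissions (default 690).
#' @param n_panel Records with a complete TSH+FT4 panel (default 288).
#' @param n_full_panel Records that additionally have FT3 (default 169).
#' @param n_tsh Records with at least TSH observed (default scales the
#'   registry's 411/690; must be >= `n_panel`).
#' @param n_outcome Records with outcome (death indicator + follow-up)
#'   available (default scales the registry's 237/288 follow-up fraction).
#' @param weights Mixture weights (default 0.27/0.12/0.61).
#' @param cluster_loghr Per-component log hazard multipliers (default
#'   `c(-0.7, 0.4, 0)`: low-output protective, high-output adverse).
#' @param effects Named list of covariate log-hazard effects:
#'   `ft3` (per pmol/L, centred at 4), `ef` (per EF percent, centred at 44),
#'   `atrial_fibrillation`, `malignancy`. Set all to 0 for a null
#'   generator.
#' @param base_hazard Baseline daily hazard; the default is calibrated so
#'   that roughly 31% of followed records die within the censoring window.
#' @param censor_max Upper end of the uniform censoring window in days
#'   (default 6597).
#' @param ft3_noise Multiplicative log-normal noise SD on FT3 (default
#'   0.05).
#' @param p_levothyroxine Prevalence of levothyroxine substitution
#'   (default 0.12).
#' @param seed Integer seed; required for reproducibility.
#' @return A `thyro_cohort` tibble of `n_total` rows with the canonical
#'   columns plus `true_cluster`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_total = 100, n_panel = 80, n_full_panel = 50,
#'                           seed = 42)
#' cohort_flow(cohort)
simulate_cohort <- function(n_total = 690, n_panel = 288, n_full_panel = 169,
                            n_tsh = NULL, n_outcome = NULL,
                            weights = c(0.27, 0.12, 0.61),
                            cluster_loghr = c(-0.7, 0.4, 0),
                            effects = list(ft3 = -0.25, ef = -0.04,
                                           atrial_fibrillation = 0.74,
                                           malignancy = 0.54),
                            base_hazard = 1.05e-4,
                            censor_max = 6597,
                            ft3_noise = 0.05,
                            p_levothyroxine = 0.12,
                            seed = 1L) {
  if (n_full_panel > n_panel) stop("n_full_panel must be <= n_panel", call. = FALSE)
  if (n_panel > n_total) stop("n_panel must be <= n_total", call. = FALSE)
  if (is.null(n_tsh)) n_tsh <- min(n_total, round(n_total * 411 / 690))
  n_tsh <- max(n_tsh, n_panel)
  if (is.null(n_outcome)) n_outcome <- min(n_total, round(n_total * 237 / 288))
  if (n_outcome > n_total) stop("n_outcome must be <= n_total", call. = FALSE)
  stopifnot(abs(sum(weights) - 1) < 1e-8, all(weights > 0))

  set.seed(seed)
  params <- cluster_mixture_params()
  k <- spina_constants()

  cl <- sample.int(3, n_total, replace = TRUE, prob = weights)
  p <- params[cl, ]

  tsh <- stats::rlnorm(n_total, log(p$tsh_median),
                       sdlog_from_iqr(p$tsh_q1, p$tsh_q3))
  ft4 <- stats::rlnorm(n_total, log(p$ft4_median),
                       sdlog_from_iqr(p$ft4_q1, p$ft4_q3))
  gd <- stats::rlnorm(n_total, log(p$gd_median),
                      sdlog_from_iqr(p$gd_q1, p$gd_q3))
  # invert the deiodinase relation: the FT3 that yields the drawn GD at
  # this FT4, times multiplicative noise
  ft4_molar <- ft4 * 1e-12
  ft3_molar <- gd * 1e-9 * k$alpha_31 * ft4_molar /
    (k$beta_31 * (k$K_M1 + ft4_molar) * (1 + k$K30 * k$TBG))
  ft3 <- ft3_molar * 1e12 * exp(stats::rnorm(n_total, 0, ft3_noise))

  age <- pmin(100, pmax(18, stats::rnorm(n_total, p$age_mean, p$age_sd)))
  initial_ef <- pmin(80, pmax(10, stats::rnorm(n_total, p$ef_mean, p$ef_sd)))
  sex <- ifelse(stats::runif(n_total) < p$p_female, "female", "male")
  bern <- function(prob) stats::runif(n_total) < prob

  on_levothyroxine <- bern(p_levothyroxine)
  on_thyroid_medication <- on_levothyroxine | bern(0.12)

  atrial_fibrillation <- bern(p$p_atrial_fibrillation)
  malignancy <- bern(p$p_malignancy)
  trigger_physical <- bern(p$p_trigger_physical)
  hypertension <- bern(0.57)
  diabetes <- bern(0.13)
  hypercholesterolemia <- bern(0.24)
  smoking <- bern(0.24)
  neurological <- bern(0.24)
  psychiatric <- bern(0.11)
  cad <- bern(0.17)
  trigger_stressful <- bern(0.72)
  trigger_emotional <- bern(0.37)
  creatinine <- stats::rlnorm(n_total, log(85), sdlog_from_iqr(70, 105))
  ballooning <- sample(BALLOONING_LEVELS, n_total, replace = TRUE,
                       prob = c(0.74, 0.20, 0.02, 0.04))

  # in-hospital complications: shock and oedema depend on the thyroid state
  cardiogenic_shock <- stats::runif(n_total) <
    stats::plogis(stats::qlogis(0.10) - 0.5 * (ft3 - 4) - 0.05 * (initial_ef - 44))
  pulmonary_oedema <- stats::runif(n_total) <
    stats::plogis(stats::qlogis(0.10) + 0.06 * (ft4 - 15))
  catecholamine_use <- stats::runif(n_total) < ifelse(cardiogenic_shock, 0.8, 0.05)
  circulatory_support <- stats::runif(n_total) < ifelse(cardiogenic_shock, 0.3, 0.01)
  stroke <- bern(0.04)
  cpr <- bern(0.05)
  invasive_ventilation <- bern(0.08)
  malignant_arrhythmia <- bern(0.08)
  lv_thrombus <- bern(0.03)

  lp <- cluster_loghr[cl] +
    effects$ft3 * (ft3 - 4) +
    effects$ef * (initial_ef - 44) +
    effects$atrial_fibrillation * atrial_fibrillation +
    effects$malignancy * malignancy
  hazard <- base_hazard * exp(lp)
  t_death <- stats::rexp(n_total, rate = hazard)
  t_censor <- stats::runif(n_total, 30, censor_max)
  died <- t_death <= t_censor
  followup_days <- round(pmin(t_death, t_censor))

  # completely-at-random panel/outcome missingness to the configured counts
  tsh_rows <- sample.int(n_total, n_tsh)
  panel_rows <- sample(tsh_rows, n_panel)
  full_rows <- sample(panel_rows, n_full_panel)
  outcome_rows <- sample.int(n_total, n_outcome)
  tsh[-tsh_rows] <- NA
  ft4[-panel_rows] <- NA
  ft3[-full_rows] <- NA
  died[-outcome_rows] <- NA
  followup_days[-outcome_rows] <- NA

  cohort <- tibble::tibble(
    patient_id = sprintf("SYN%04d", seq_len(n_total)),
    tsh = tsh, ft4 = ft4, ft3 = ft3,
    on_levothyroxine = on_levothyroxine,
    on_thyroid_medication = on_thyroid_medication,
    age = age, sex = sex,
    hypertension = hypertension, diabetes = diabetes,
    hypercholesterolemia = hypercholesterolemia, smoking = smoking,
    atrial_fibrillation = atrial_fibrillation, malignancy = malignancy,
    neurological = neurological, psychiatric = psychiatric, cad = cad,
    trigger_stressful = trigger_stressful, trigger_physical = trigger_physical,
    trigger_emotional = trigger_emotional,
    creatinine = creatinine, ballooning = ballooning, initial_ef = initial_ef,
    died = died, followup_days = followup_days,
    cardiogenic_shock = cardiogenic_shock, pulmonary_oedema = pulmonary_oedema,
    catecholamine_use = catecholamine_use, stroke = stroke, cpr = cpr,
    circulatory_support = circulatory_support,
    invasive_ventilation = invasive_ventilation,
    malignant_arrhythmia = malignant_arrhythmia, lv_thrombus = lv_thrombus,
    true_cluster = cl
  )
  attr(cohort, "generator_config") <- list(
    n_total = n_total, n_panel = n_panel, n_full_panel = n_full_panel,
    n_tsh = n_tsh, n_outcome = n_outcome, weights = weights,
    cluster_loghr = cluster_loghr, effects = effects,
    base_hazard = base_hazard, censor_max = censor_max,
    ft3_noise = ft3_noise, p_levothyroxine = p_levothyroxine, seed = seed
  )
  class(cohort) <- c("thyro_cohort", class(cohort))
  cohort
}

#' Write the generator configuration sidecar
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cohort, path) {
  cfg <- attr(cohort, "generator_config")
  if (is.null(cfg)) stop("cohort has no generator_config attribute", call. = FALSE)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Monte-Carlo power of the Wilcoxon-Mann-Whitney test
#'
#' Simulates two Gaussian groups separated by a location shift and reports
#' the fraction of replicates in which the two-sided U test rejects at
#' `alpha` — the empirical power (or the empirical size when `effect = 0`).
#'
#' @param effect Location shift between the groups, in units of the group
#'   SD.
#' @param n_per_group Sample size per group (default 50).
#' @param alpha Significance level (default 0.05).
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @param sd Group standard deviation (default 1).
#' @return A one-row tibble with `power`, `se` (binomial standard error),
#'   `reps`, `n_per_group`, `effect`, `alpha`.
#' @export
#' @examples
#' wmw_power(effect = 2, n_per_group = 20, reps = 200, seed = 1)
wmw_power <- function(effect, n_per_group = 50, alpha = 0.05, reps = 1000,
                      seed = 1L, sd = 1) {
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  set.seed(seed)
  rejections <- vapply(seq_len(reps), function(i) {
    x <- stats::rnorm(n_per_group, 0, sd)
    y <- stats::rnorm(n_per_group, effect, sd)
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value < alpha
  }, logical(1))
  pw <- mean(rejections)
  tibble::tibble(power = pw, se = sqrt(pw * (1 - pw) / reps), reps = reps,
                 n_per_group = n_per_group, effect = effect, alpha = alpha)
}
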