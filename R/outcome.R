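#' Compare variables between two groups (survivor/non-survivor style tables)
#'
#' Continuous variables are compared with the two-sided Wilcoxon-Mann-Whitney
#' U test (exact where sample size permits and no ties, otherwise the
#' normal approximation with tie correction); categorical variables with the
#' chi-squared test, replaced by Fisher's exact test whenever any expected
#' cell count of the 2x2 table is below 5. Summaries are mean +/- SD when
#' both groups pass a Shapiro-Wilk normality check, otherwise median
#' (1st-3rd quartile). For continuous variables with positive medians the
#' ratio of medians (flagged group over reference group) is reported with a
#' bootstrap confidence interval.
#'
#' @param cohort A cohort tibble.
#' @param grouping Name of a logical column defining the two groups (e.g.
#'   `"died"`); rows with the flag missing are dropped.
#' @param variables Character vector of columns to compare; absent columns
#'   are skipped with a warning. Missing values are dropped pairwise, with
#'   per-variable n reported.
#' @param rom_reps Bootstrap replicates for the ratio-of-medians CI
#'   (default 2000); `0` skips the CI.
#' @param seed Seed for the bootstrap.
#' @return A tibble with one row per variable: group sizes, formatted group
#'   summaries, the test used, its p-value, and where applicable the ratio
#'   of medians with its CI (flagged/reference).
#' @export
compare_groups <- function(cohort, grouping, variables, rom_reps = 2000,
                           seed = NULL) {
  stopifnot(grouping %in% names(cohort))
  g <- cohort[[grouping]]
  rows <- purrr::map(variables, function(v) {
    if (!v %in% names(cohort)) {
      warning("variable '", v, "' not found; skipped", call. = FALSE)
      return(NULL)
    }
    x <- cohort[[v]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; gg <- g[keep]
    x_ref <- x[!gg]; x_flag <- x[gg]
    if (length(x_ref) == 0 || length(x_flag) == 0) {
      warning("variable '", v, "' has an empty group; skipped", call. = FALSE)
      return(NULL)
    }
    if (is.numeric(x)) {
      wt <- suppressWarnings(stats::wilcox.test(x_flag, x_ref, exact = NULL))
      normal_ish <- function(z) {
        if (length(z) < 3 || length(z) > 5000 || length(unique(z)) == 1) return(FALSE)
        stats::shapiro.test(z)$p.value > 0.05
      }
      fmt <- if (normal_ish(x_ref) && normal_ish(x_flag)) {
        function(z) sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
      } else {
        function(z) sprintf("%.2f (%.2f-%.2f)", stats::median(z),
                            stats::quantile(z, 0.25), stats::quantile(z, 0.75))
      }
      rom <- c(NA_real_, NA_real_, NA_real_)
      if (stats::median(x_ref) > 0 && stats::median(x_flag) > 0) {
        ci <- ratio_of_medians_ci(x_flag, x_ref, reps = rom_reps, seed = seed)
        rom <- c(ci$estimate, ci$conf_low, ci$conf_high)
      }
      tibble::tibble(
        variable = v, type = "continuous",
        n_ref = length(x_ref), n_flag = length(x_flag),
        summary_ref = fmt(x_ref), summary_flag = fmt(x_flag),
        test = "Wilcoxon-Mann-Whitney", p_value = wt$p.value,
        ratio_of_medians = rom[1], rom_low = rom[2], rom_high = rom[3]
      )
    } else {
      xf <- factor(as.logical(x), levels = c(FALSE, TRUE))
      tab <- table(xf, factor(gg, levels = c(FALSE, TRUE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        test <- "Fisher exact"; p <- ft$p.value
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        test <- "chi-squared"; p <- ct$p.value
      }
      pct <- function(col) sprintf("%d (%.1f%%)", tab["TRUE", col],
                                   100 * tab["TRUE", col] / sum(tab[, col]))
      tibble::tibble(
        variable = v, type = "categorical",
        n_ref = sum(tab[, "FALSE"]), n_flag = sum(tab[, "TRUE"]),
        summary_ref = pct("FALSE"), summary_flag = pct("TRUE"),
        test = test, p_value = p,
        ratio_of_medians = NA_real_, rom_low = NA_real_, rom_high = NA_real_
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Ratio of medians with a bootstrap confidence interval
#'
#' Point estimate `median(x) / median(y)`; the confidence interval is the
#' percentile bootstrap over `reps` resamples drawn independently within
#' each group.
#'
#' @param x,y Numeric samples (numerator and denominator groups).
#' @param level Confidence level (default 0.95).
#' @param reps Bootstrap replicates (default 2000); `0` returns only the
#'   point estimate.
#' @param seed Optional seed for the resampling.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `level`.
#' @export
ratio_of_medians_ci <- function(x, y, level = 0.95, reps = 2000, seed = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty",
                                             call. = FALSE)
  if (stats::median(y) == 0) stop("denominator median is 0; ratio undefined",
                                  call. = FALSE)
  est <- stats::median(x) / stats::median(y)
  lo <- hi <- NA_real_
  if (reps > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    boots <- vapply(seq_len(reps), function(i) {
      stats::median(sample(x, replace = TRUE)) /
        stats::median(sample(y, replace = TRUE))
    }, numeric(1))
    alpha <- (1 - level) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  tibble::tibble(estimate = est, conf_low = lo, conf_high = hi, level = level)
}

#' Optimal dichotomization cutoffs from phi statistics and Youden's J
#'
#' Returns the cutoff maximizing the absolute phi coefficient of the
#' induced 2x2 table and the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1, with the risk direction (which side
#' of the cutoff predicts the event) recorded explicitly.
#'
#' Every attained marker value `v` is evaluated under the rule
#' `marker >= v predicts the event`; the opposite rule (`marker < v`) is
#' its complement and simply mirrors the signs of phi and J, so both
#' directions are covered by one sweep and every distinct dichotomization
#' of the sample is visited (a threshold between two attained values
#' induces the same split as the upper value). Reported cutoffs are
#' therefore always attained data values; equal-scoring thresholds resolve
#' to the lowest such value. With `direction = "greater"`,
#' `marker >= cutoff` predicts the event; with `"less"`,
#' `marker < cutoff` does.
#'
#' @param marker Numeric marker values.
#' @param outcome Logical event indicator (e.g. death), same length.
#' @return An object of class `thyro_cutoff`: list with `cutoff_phi`,
#'   `phi`, `direction_phi`, `cutoff_youden`, `youden`, `direction_youden`
#'   and `roc` (tibble of threshold, sensitivity, specificity, phi, J for
#'   the `marker >= threshold` rule).
#' @export
optimal_cutoffs <- function(marker, outcome) {
  keep <- !is.na(marker) & !is.na(outcome)
  marker <- marker[keep]; outcome <- as.logical(outcome[keep])
  if (length(unique(marker)) < 2) stop("marker needs at least 2 distinct values",
                                       call. = FALSE)
  if (!any(outcome) || all(outcome)) stop("degenerate outcome: both classes required",
                                          call. = FALSE)
  thresholds <- sort(unique(marker))
  P <- sum(outcome); N <- sum(!outcome)
  stats_at <- function(t) {
    pred <- marker >= t
    tp <- sum(pred & outcome); fp <- sum(pred & !outcome)
    fn <- P - tp; tn <- N - fp
    denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    phi <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    c(sens = tp / P, spec = tn / N, phi = phi, J = tp / P + tn / N - 1)
  }
  m <- t(vapply(thresholds, stats_at, numeric(4)))
  roc <- tibble::tibble(threshold = thresholds, sensitivity = m[, "sens"],
                        specificity = m[, "spec"], phi = m[, "phi"],
                        youden = m[, "J"])
  best_phi <- which.max(abs(m[, "phi"]))
  best_j <- which.max(abs(m[, "J"]))
  structure(
    list(
      cutoff_phi = thresholds[best_phi],
      phi = unname(abs(m[best_phi, "phi"])),
      direction_phi = if (m[best_phi, "phi"] >= 0) "greater" else "less",
      cutoff_youden = thresholds[best_j],
      youden = unname(abs(m[best_j, "J"])),
      direction_youden = if (m[best_j, "J"] >= 0) "greater" else "less",
      roc = roc,
      n = length(marker), n_events = P
    ),
    class = "thyro_cutoff"
  )
}

#' @export
print.thyro_cutoff <- function(x, ...) {
  cat(sprintf("phi cutoff: %g (|phi| = %.3f, risk %s)\n",
              x$cutoff_phi, x$phi, x$direction_phi))
  cat(sprintf("Youden cutoff: %g (J = %.3f, risk %s)\n",
              x$cutoff_youden, x$youden, x$direction_youden))
  invisible(x)
}

#' Cutoffs for a set of cohort markers with respect to survival
#'
#' @param cohort A cohort tibble with `died` and the marker columns.
#' @param markers Character vector of marker column names.
#' @return A tibble with one row per marker (phi and Youden cutoffs,
#'   statistics and risk directions).
#' @export
survival_cutoffs <- function(cohort,
                             markers = c("tsh", "ft4", "ft3", "spina_gt",
                                         "spina_gd")) {
  purrr::map_dfr(markers, function(mk) {
    if (!mk %in% names(cohort)) {
      warning("marker '", mk, "' not found; skipped", call. = FALSE)
      return(NULL)
    }
    co <- optimal_cutoffs(cohort[[mk]], cohort$died)
    tibble::tibble(
      marker = mk, n = co$n, n_events = co$n_events,
      cutoff_phi = co$cutoff_phi, phi = co$phi,
      direction_phi = co$direction_phi,
      cutoff_youden = co$cutoff_youden, youden = co$youden,
      direction_youden = co$direction_youden
    )
  })
}

#' Kaplan-Meier survival curves with a log-rank comparison
#'
#' Product-limit estimator per stratum, with the day of disease onset as
#' time origin (day 0) and right censoring at the end of follow-up. When a
#' stratifier is supplied, strata are compared with the log-rank test;
#' with no events the log-rank statistic is reported as `NA`.
#'
#' @param cohort A cohort tibble with `followup_days` and `died`.
#' @param stratum Optional name of a column to stratify by; missing values
#'   of the stratifier (and empty strata) are dropped with a message.
#' @return An object of class `thyro_km`: list with `fit` (the
#'   `survival::survfit` object), `steps` (tidy step-function tibble),
#'   `logrank_chisq`, `logrank_df`, `logrank_p` and `n`.
#' @export
kaplan_meier <- function(cohort, stratum = NULL) {
  keep <- !is.na(cohort$followup_days) & !is.na(cohort$died)
  if (!is.null(stratum)) keep <- keep & !is.na(cohort[[stratum]])
  data <- cohort[keep, , drop = FALSE]
  if (nrow(data) < nrow(cohort)) {
    message("Kaplan-Meier: dropped ", nrow(cohort) - nrow(data),
            " records with missing outcome or stratum")
  }
  surv <- survival::Surv(data$followup_days, data$died)
  chisq <- df <- p <- NA_real_
  if (is.null(stratum)) {
    fit <- survival::survfit(surv ~ 1, data = data)
  } else {
    data$..stratum <- factor(data[[stratum]])
    data$..stratum <- droplevels(data$..stratum)
    fit <- survival::survfit(surv ~ ..stratum, data = data)
    if (sum(data$died) > 0 && nlevels(data$..stratum) > 1) {
      sd <- survival::survdiff(surv ~ ..stratum, data = data)
      df <- length(sd$n) - 1
      chisq <- sd$chisq
      p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
    } else {
      message("log-rank undefined (no events or a single stratum)")
    }
  }
  sm <- summary(fit)
  nstep <- length(sm$time)
  steps <- tibble::tibble(
    stratum = if (is.null(sm$strata)) rep("all", nstep) else
      sub("^\\.\\.stratum=", "", as.character(sm$strata)),
    time = as.numeric(sm$time),
    n_risk = as.numeric(sm$n.risk),
    n_event = as.numeric(sm$n.event),
    survival = if (is.null(sm$surv)) rep(NA_real_, nstep) else
      as.numeric(sm$surv),
    std_err = if (is.null(sm$std.err)) rep(NA_real_, nstep) else
      as.numeric(sm$std.err)
  )
  structure(
    list(fit = fit, steps = steps, logrank_chisq = chisq, logrank_df = df,
         logrank_p = p, n = nrow(data), stratum = stratum),
    class = "thyro_km"
  )
}

#' @export
print.thyro_km <- function(x, ...) {
  cat("Kaplan-Meier estimate, n =", x$n)
  if (!is.null(x$stratum)) cat(", stratified by", x$stratum)
  cat("\n")
  if (!is.na(x$logrank_chisq)) {
    cat(sprintf("log-rank chi-squared = %.2f (df %d), p = %.2g\n",
                x$logrank_chisq, x$logrank_df, x$logrank_p))
  }
  invisible(x)
}

#' Step-curve plot for a Kaplan-Meier result
#'
#' @param object A `thyro_km` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thyro_km
#' @export
autoplot.thyro_km <- function(object, ...) {
  steps <- dplyr::bind_rows(
    dplyr::distinct(dplyr::mutate(object$steps, time = 0, survival = 1),
                    .data$stratum, .keep_all = TRUE),
    object$steps
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days since onset", y = "survival",
                  colour = object$stratum %||% "stratum") +
    ggplot2::theme_minimal()
}

cox_default_predictors <- function() {
  c("tsh", "ft4", "ft3", "age", "sex_female", "hypertension", "diabetes",
    "hypercholesterolemia", "smoking", "atrial_fibrillation", "malignancy",
    "neurological", "psychiatric", "trigger_stressful", "trigger_physical",
    "trigger_emotional", "creatinine", "ballooning_apical",
    "ballooning_midventricular", "ballooning_basal", "ballooning_focal",
    "initial_ef")
}

# expand sex/ballooning into the indicator columns the predictor list uses
expand_cox_covariates <- function(cohort) {
  if (!"sex_female" %in% names(cohort) && "sex" %in% names(cohort)) {
    cohort$sex_female <- cohort$sex == "female"
  }
  if ("ballooning" %in% names(cohort)) {
    for (lv in BALLOONING_LEVELS) {
      col <- paste0("ballooning_", lv)
      if (!col %in% names(cohort)) cohort[[col]] <- cohort$ballooning == lv
    }
  }
  cohort
}

#' Univariable, minimal multivariable and frailty Cox models for survival
#'
#' Fits a univariable proportional-hazards model per candidate predictor;
#' predictors with univariable p below `entry_p` enter a maximal
#' multivariable model, which is simplified stepwise by repeatedly
#' eliminating the least significant term (equal p broken by later position
#' in the predictor list) until every remaining term has p below `stay_p`.
#' A hierarchical variant refits the minimal model with a shared gamma
#' frailty over sex-by-age-decade clusters, treating sex and age as
#' potentially confounding group effects rather than fixed covariates.
#' Calculated homeostasis indices and medication flags are never entered
#' into the multivariable model, to avoid spurious correlations with their
#' own inputs. Terms whose fit is unstable (monotone likelihood / sparse
#' data, detected via convergence warnings or extreme standard errors) are
#' flagged `"unstable (sparse data)"` but still reported with their CIs.
#'
#' @param cohort A cohort tibble (ballooning and sex are expanded to
#'   indicators automatically).
#' @param predictors Candidate predictor columns (default: the predefined
#'   clinical list — thyroid panel, demographics, comorbidities, triggers,
#'   creatinine, ballooning pattern, initial EF).
#' @param entry_p Univariable p threshold to enter the multivariable model
#'   (default 0.10).
#' @param stay_p Retention threshold of the stepwise minimal model
#'   (default 0.05).
#' @param frailty Also fit the frailty-adjusted minimal model (default
#'   `TRUE`).
#' @return An object of class `thyro_cox`: list of tibbles `univariable`,
#'   `multivariable`, `frailty` (each: term, n, hr, conf_low, conf_high,
#'   p_value, flag), plus `entrants` and the thresholds used.
#' @export
cox_models <- function(cohort, predictors = cox_default_predictors(),
                       entry_p = 0.10, stay_p = 0.05, frailty = TRUE) {
  cohort <- expand_cox_covariates(cohort)
  cohort <- cohort[!is.na(cohort$followup_days) & !is.na(cohort$died), ,
                   drop = FALSE]
  predictors <- predictors[predictors %in% names(cohort)]
  if (length(predictors) == 0) stop("no candidate predictors present",
                                    call. = FALSE)

  fit_cox <- function(data, terms, frailty_col = NULL) {
    rhs <- paste(terms, collapse = " + ")
    if (!is.null(frailty_col)) {
      rhs <- paste(rhs, sprintf("+ frailty(%s)", frailty_col))
    }
    f <- stats::as.formula(paste("survival::Surv(followup_days, died) ~", rhs))
    unstable <- FALSE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(f, data = data), error = function(e) NULL),
      warning = function(w) {
        unstable <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    list(fit = fit, unstable = unstable)
  }

  tidy_fit <- function(res, terms, n) {
    if (is.null(res$fit)) {
      return(tibble::tibble(term = terms, n = n, estimate = NA_real_,
                            hr = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, p_value = NA_real_,
                            flag = "fit failed"))
    }
    sm <- summary(res$fit)
    coefs <- sm$coefficients
    keep <- rownames(coefs) %in% c(terms, paste0(terms, "TRUE"))
    coefs <- coefs[keep, , drop = FALSE]
    se_col <- if ("se(coef)" %in% colnames(coefs)) "se(coef)" else "robust se"
    se <- coefs[, se_col]
    beta <- coefs[, "coef"]
    pcol <- grep("^Pr|^p$", colnames(coefs), value = TRUE)[1]
    term_names <- sub("TRUE$", "", rownames(coefs))
    unstable_term <- abs(beta) > 10 | se > 10
    tibble::tibble(
      term = term_names, n = n,
      estimate = unname(beta),
      hr = exp(unname(beta)),
      conf_low = exp(unname(beta - 1.96 * se)),
      conf_high = exp(unname(beta + 1.96 * se)),
      p_value = unname(coefs[, pcol]),
      flag = ifelse(res$unstable | unstable_term, "unstable (sparse data)", "")
    )
  }

  uni <- purrr::map_dfr(predictors, function(p) {
    data <- cohort[!is.na(cohort[[p]]), , drop = FALSE]
    if (nrow(data) == 0 || sum(data$died) == 0) {
      return(tibble::tibble(term = p, n = nrow(data), estimate = NA_real_,
                            hr = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, p_value = NA_real_,
                            flag = "no events"))
    }
    tidy_fit(fit_cox(data, p), p, nrow(data))
  })

  entrants <- uni$term[!is.na(uni$p_value) & uni$p_value < entry_p]
  multi <- tibble::tibble()
  minimal_terms <- character(0)
  n_multi <- 0L
  if (length(entrants) > 0) {
    data <- cohort[stats::complete.cases(cohort[, c("followup_days", "died",
                                                    entrants)]), , drop = FALSE]
    n_multi <- nrow(data)
    terms <- entrants
    repeat {
      res <- fit_cox(data, terms)
      tab <- tidy_fit(res, terms, n_multi)
      worst <- tab$p_value
      if (all(is.na(worst))) break
      if (max(worst, na.rm = TRUE) < stay_p || length(terms) == 1) {
        multi <- tab
        minimal_terms <- terms
        break
      }
      # eliminate the least significant; equal p -> later list position
      pmax_val <- max(worst, na.rm = TRUE)
      cand <- tab$term[!is.na(worst) & worst == pmax_val]
      drop_term <- cand[which.max(match(cand, predictors))]
      terms <- setdiff(terms, drop_term)
      if (length(terms) == 0) break
    }
  }

  frail <- tibble::tibble()
  if (frailty && length(minimal_terms) > 0) {
    data <- cohort[stats::complete.cases(cohort[, c("followup_days", "died",
                                                    minimal_terms)]), ,
                   drop = FALSE]
    if (all(c("sex", "age") %in% names(data))) {
      data$..frailty_group <- interaction(
        data$sex, cut(data$age, breaks = seq(0, 120, by = 10)), drop = TRUE)
      fixed <- setdiff(minimal_terms, c("age", "sex_female"))
      if (length(fixed) > 0) {
        res <- fit_cox(data, fixed, frailty_col = "..frailty_group")
        frail <- tidy_fit(res, fixed, nrow(data))
      }
    }
  }

  structure(
    list(univariable = uni, entrants = entrants, multivariable = multi,
         frailty = frail, n_multivariable = n_multi,
         entry_p = entry_p, stay_p = stay_p),
    class = "thyro_cox"
  )
}

#' @export
print.thyro_cox <- function(x, ...) {
  cat("Cox proportional-hazards stack\n")
  cat("univariable terms:", nrow(x$univariable), "\n")
  cat("entrants (p <", x$entry_p, "):", paste(x$entrants, collapse = ", "), "\n")
  if (nrow(x$multivariable) > 0) {
    cat("minimal model (p <", x$stay_p, "):\n")
    print(x$multivariable)
  }
  invisible(x)
}

#' Composite in-hospital complication endpoint
#'
#' Builds the composite endpoint (malignant arrhythmia, thromboembolic
#' event or stroke, pulmonary congestion, or cardiogenic shock with
#' catecholamine use and/or circulatory assist) and compares thyroid
#' markers between patients with and without the composite and its main
#' individual components.
#'
#' @param cohort A cohort tibble with the complication flags.
#' @param markers Thyroid markers to compare (default panel + calculated
#'   indices present in the cohort).
#' @param rom_reps,seed Passed to [compare_groups()].
#' @return A list with `cohort` (with a `composite_endpoint` column) and
#'   `comparisons` (tibble of [compare_groups()] rows, one block per
#'   endpoint, identified by an `endpoint` column).
#' @export
composite_endpoint <- function(cohort,
                               markers = intersect(
                                 c("tsh", "ft4", "ft3", "spina_gt", "spina_gd",
                                   "jti", "ttsi", "tfqi"), names(cohort)),
                               rom_reps = 2000, seed = NULL) {
  flag <- function(col) {
    v <- cohort[[col]]
    if (is.null(v)) rep(NA, nrow(cohort)) else v
  }
  or_na <- function(...) {
    m <- cbind(...)
    out <- apply(m, 1, function(r) {
      if (all(is.na(r))) NA else any(r, na.rm = TRUE)
    })
    as.logical(out)
  }
  shock_supported <- flag("cardiogenic_shock") &
    or_na(flag("catecholamine_use"), flag("circulatory_support"))
  cohort$composite_endpoint <- or_na(
    flag("malignant_arrhythmia"), flag("stroke"), flag("lv_thrombus"),
    flag("pulmonary_oedema"), shock_supported
  )
  endpoints <- c("composite_endpoint", "cardiogenic_shock", "pulmonary_oedema",
                 "catecholamine_use", "stroke")
  comparisons <- purrr::map_dfr(endpoints, function(ep) {
    if (!ep %in% names(cohort) || all(is.na(cohort[[ep]]))) return(NULL)
    res <- compare_groups(cohort, ep, markers, rom_reps = rom_reps, seed = seed)
    if (nrow(res) > 0) res$endpoint <- ep
    res
  })
  list(cohort = cohort, comparisons = comparisons)
}
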