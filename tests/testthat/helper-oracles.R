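# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles share no code with the implementation paths they check.

# exhaustive k-medoids optimum: minimal total distance over all medoid subsets
brute_pam_cost <- function(x, k) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  subsets <- utils::combn(nrow(x), k)
  min(apply(subsets, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min))))
}

# exhaustive cutoff search: best |phi| and best |J| over every
# dichotomization of the sample (all subsets of the form marker >= v and
# their complements)
brute_cutoffs <- function(marker, outcome) {
  outcome <- as.logical(outcome)
  P <- sum(outcome); N <- sum(!outcome)
  best_phi <- 0; best_j <- -Inf
  for (v in sort(unique(marker))) {
    for (pred in list(marker >= v, marker < v)) {
      tp <- sum(pred & outcome); fp <- sum(pred & !outcome)
      fn <- P - tp; tn <- N - fp
      denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      phi <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
      j <- tp / P + tn / N - 1
      best_phi <- max(best_phi, abs(phi))
      best_j <- max(best_j, j)
    }
  }
  list(phi = best_phi, youden = best_j)
}

# exhaustive two-sided Wilcoxon-Mann-Whitney p-value: permutation
# distribution of the rank sum over all group relabellings
perm_wmw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  centre <- n * (length(pooled) + 1) / 2
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-9)
}

# minimal hand-built cohort covering the canonical columns
tiny_cohort <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    tsh = c(1.0, 2.8, NA, 0.4),
    ft4 = c(14.1, 13.5, 15.0, NA),
    ft3 = c(4.0, NA, 3.2, 4.4),
    on_levothyroxine = c(FALSE, TRUE, FALSE, FALSE),
    on_thyroid_medication = c(FALSE, TRUE, FALSE, FALSE),
    age = c(68, 72, 60, 81),
    sex = c("female", "female", "male", "female"),
    hypertension = c(TRUE, FALSE, TRUE, TRUE),
    diabetes = c(FALSE, FALSE, TRUE, FALSE),
    hypercholesterolemia = c(FALSE, TRUE, FALSE, FALSE),
    smoking = c(FALSE, FALSE, TRUE, FALSE),
    atrial_fibrillation = c(FALSE, TRUE, FALSE, FALSE),
    malignancy = c(FALSE, FALSE, FALSE, TRUE),
    neurological = c(FALSE, FALSE, FALSE, FALSE),
    psychiatric = c(TRUE, FALSE, FALSE, FALSE),
    cad = c(FALSE, FALSE, TRUE, FALSE),
    trigger_stressful = c(TRUE, TRUE, FALSE, TRUE),
    trigger_physical = c(FALSE, TRUE, FALSE, FALSE),
    trigger_emotional = c(TRUE, FALSE, FALSE, TRUE),
    creatinine = c(80, 95, NA, 120),
    ballooning = c("apical", "midventricular", "apical", NA),
    initial_ef = c(45, 38, 50, NA),
    died = c(FALSE, TRUE, FALSE, TRUE),
    followup_days = c(1200, 30, 2500, 400),
    cardiogenic_shock = c(FALSE, TRUE, FALSE, FALSE),
    pulmonary_oedema = c(FALSE, FALSE, FALSE, TRUE),
    catecholamine_use = c(FALSE, TRUE, FALSE, FALSE),
    stroke = c(FALSE, FALSE, FALSE, FALSE),
    cpr = c(FALSE, FALSE, FALSE, FALSE),
    circulatory_support = c(FALSE, FALSE, FALSE, FALSE),
    invasive_ventilation = c(FALSE, TRUE, FALSE, FALSE),
    malignant_arrhythmia = c(FALSE, FALSE, FALSE, FALSE),
    lv_thrombus = c(FALSE, FALSE, FALSE, FALSE)
  )
}
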