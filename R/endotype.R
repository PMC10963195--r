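ENDOTYPE_LEVELS <- c("normal", "tacitus", "type2_allostatic",
                     "primary_thyrotoxicosis", "primary_hypothyroidism",
                     "unclassifiable")

#' Classify the pattern of thyroid function at admission
#'
#' Assigns each admission panel one of five thyroid-function patterns
#' relative to the configured laboratory reference ranges, with a fixed rule
#' precedence so the classes form a deterministic partition:
#'
#' 1. **primary_thyrotoxicosis** — suppressed TSH with elevated FT4.
#' 2. **type2_allostatic** — elevated FT4 with non-suppressed TSH (the
#'    stress-driven upward shift of the feedback set point). With
#'    `type2_variant = "strict"` TSH must itself be elevated; the default
#'    `"nonsuppressed"` variant also admits in-range or elevated TSH,
#'    provided FT3 is not reduced (a reduced FT3 routes to TACITUS).
#' 3. **primary_hypothyroidism** — elevated TSH with reduced FT4.
#' 4. **tacitus** — reduced FT3 with non-elevated TSH: type 1 allostatic
#'    load of critical illness (non-thyroidal illness / low-T3 syndrome).
#' 5. **normal** — all available analytes within range. A record with
#'    normal TSH and FT4 but no FT3 measurement is classified normal by
#'    available evidence and flagged in the reason column.
#'
#' Panels matching none of the rules (for instance suppressed TSH with
#' in-range FT4 and FT3) are `unclassifiable` with a documented reason, as
#' is any record missing TSH or FT4.
#'
#' @param tsh,ft4,ft3 Admission concentrations (vectors; mIU/L, pmol/L,
#'   pmol/L). `ft3` may be `NA`.
#' @param ranges A [reference_ranges()] object.
#' @param type2_variant `"nonsuppressed"` (default) or `"strict"`.
#' @return A tibble with columns `endotype` (factor over the five labels
#'   plus `unclassifiable`) and `reason` (character, `NA` unless flagged).
#' @export
#' @examples
#' classify_endotype(c(0.1, 1.2, 1.2), c(30, 14, 14), c(4, 2.0, 4.2))
classify_endotype <- function(tsh, ft4, ft3 = NULL,
                              ranges = reference_ranges(),
                              type2_variant = c("nonsuppressed", "strict")) {
  type2_variant <- match.arg(type2_variant)
  n <- length(tsh)
  stopifnot(length(ft4) == n)
  if (is.null(ft3)) ft3 <- rep(NA_real_, n)
  stopifnot(length(ft3) == n)
  r <- ranges

  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  incomplete <- is.na(tsh) | is.na(ft4)
  label[incomplete] <- "unclassifiable"
  reason[incomplete] <- "incomplete panel"

  tsh_low  <- !is.na(tsh) & tsh < r$tsh_low
  tsh_high <- !is.na(tsh) & tsh > r$tsh_high
  tsh_in   <- !is.na(tsh) & !tsh_low & !tsh_high
  ft4_low  <- !is.na(ft4) & ft4 < r$ft4_low
  ft4_high <- !is.na(ft4) & ft4 > r$ft4_high
  ft4_in   <- !is.na(ft4) & !ft4_low & !ft4_high
  ft3_low  <- !is.na(ft3) & ft3 < r$ft3_low
  ft3_in   <- !is.na(ft3) & ft3 >= r$ft3_low & ft3 <= r$ft3_high

  open <- function() is.na(label)

  idx <- open() & tsh_low & ft4_high
  label[idx] <- "primary_thyrotoxicosis"

  idx <- open() & ft4_high & !ft3_low &
    (if (type2_variant == "strict") tsh_high else (tsh_high | tsh_in))
  label[idx] <- "type2_allostatic"

  idx <- open() & tsh_high & ft4_low
  label[idx] <- "primary_hypothyroidism"

  idx <- open() & ft3_low & !tsh_high
  label[idx] <- "tacitus"

  idx <- open() & tsh_in & ft4_in & ft3_in
  label[idx] <- "normal"

  idx <- open() & tsh_in & ft4_in & is.na(ft3)
  label[idx] <- "normal"
  reason[idx] <- "FT3 not measured; normal by available evidence"

  idx <- open()
  label[idx] <- "unclassifiable"
  reason[idx] <- "pattern not covered by the rule set"

  tibble::tibble(
    endotype = factor(label, levels = ENDOTYPE_LEVELS),
    reason = reason
  )
}

#' Append the thyroid-function endotype to a cohort
#'
#' @param cohort A cohort tibble with `tsh`, `ft4`, `ft3` columns.
#' @inheritParams classify_endotype
#' @return The cohort with `endotype` and `endotype_reason` columns.
#' @export
add_endotype <- function(cohort, ranges = reference_ranges(),
                         type2_variant = "nonsuppressed") {
  cls <- classify_endotype(cohort$tsh, cohort$ft4, cohort$ft3,
                           ranges = ranges, type2_variant = type2_variant)
  dplyr::mutate(cohort, endotype = cls$endotype, endotype_reason = cls$reason)
}

#' Frequency table of thyroid-function endotypes
#'
#' Counts and percentages per endotype, overall or stratified by a grouping
#' flag (typically `died`, giving the survivor / non-survivor layout).
#' Stratified counts always sum to the overall counts.
#'
#' @param cohort A cohort tibble carrying an `endotype` column (see
#'   [add_endotype()]).
#' @param by Optional name of a logical column to stratify by (e.g.
#'   `"died"`); rows with the stratifier missing are dropped from the
#'   stratified view.
#' @param drop_unclassifiable Drop `unclassifiable` records before
#'   computing percentages (default `TRUE`, matching a classifiable-only
#'   denominator).
#' @return A tibble with columns `endotype`, `stratum` (`"overall"` or the
#'   two levels of `by`), `n` and `pct`.
#' @export
endotype_frequencies <- function(cohort, by = NULL, drop_unclassifiable = TRUE) {
  stopifnot("endotype" %in% names(cohort))
  data <- cohort
  if (drop_unclassifiable) {
    data <- dplyr::filter(data, .data$endotype != "unclassifiable")
  }
  data$endotype <- droplevels(factor(data$endotype))
  tab_of <- function(d, stratum) {
    counts <- table(d$endotype)
    tibble::tibble(
      endotype = names(counts),
      stratum = stratum,
      n = as.integer(counts),
      pct = 100 * as.integer(counts) / max(1L, sum(counts))
    )
  }
  out <- tab_of(data, "overall")
  if (!is.null(by)) {
    stopifnot(by %in% names(data))
    strat <- dplyr::filter(data, !is.na(.data[[by]]))
    for (lv in c(FALSE, TRUE)) {
      stratum_name <- paste0(by, "=", lv)
      out <- dplyr::bind_rows(out, tab_of(strat[strat[[by]] == lv, ], stratum_name))
    }
  }
  out
}
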