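#' @importFrom rlang .data
NULL

# canonical column order; concentrations internally in SI units
# (TSH mIU/L, FT4 pmol/L, FT3 pmol/L, creatinine umol/L)
COHORT_COLUMNS <- c(
  "patient_id", "tsh", "ft4", "ft3",
  "on_levothyroxine", "on_thyroid_medication",
  "age", "sex",
  "hypertension", "diabetes", "hypercholesterolemia", "smoking",
  "atrial_fibrillation", "malignancy", "neurological", "psychiatric", "cad",
  "trigger_stressful", "trigger_physical", "trigger_emotional",
  "creatinine", "ballooning", "initial_ef",
  "died", "followup_days",
  "cardiogenic_shock", "pulmonary_oedema", "catecholamine_use", "stroke",
  "cpr", "circulatory_support", "invasive_ventilation",
  "malignant_arrhythmia", "lv_thrombus"
)

COHORT_REQUIRED <- c("patient_id", "tsh", "ft4", "died", "followup_days")

COHORT_FLAGS <- c(
  "on_levothyroxine", "on_thyroid_medication",
  "hypertension", "diabetes", "hypercholesterolemia", "smoking",
  "atrial_fibrillation", "malignancy", "neurological", "psychiatric", "cad",
  "trigger_stressful", "trigger_physical", "trigger_emotional", "died",
  "cardiogenic_shock", "pulmonary_oedema", "catecholamine_use", "stroke",
  "cpr", "circulatory_support", "invasive_ventilation",
  "malignant_arrhythmia", "lv_thrombus"
)

BALLOONING_LEVELS <- c("apical", "midventricular", "basal", "focal")

# unit conversion factors from conventional to SI
FT4_NGDL_TO_PMOLL <- 12.87
FT3_PGML_TO_PMOLL <- 1.536

default_plausibility <- function() {
  list(
    tsh = c(0, 500), ft4 = c(0, 200), ft3 = c(0, 50),
    creatinine = c(0, 3000), initial_ef = c(0, 100), age = c(0, 120)
  )
}

#' Read a per-patient cohort table
#'
#' Reads an RFC-4180 CSV with one row per admission, validates it, and
#' normalizes all analyte concentrations to SI units (TSH mIU/L, FT4 pmol/L,
#' FT3 pmol/L). Files exported in conventional US units (FT4 in ng/dL, FT3
#' in pg/mL) are converted with the factors 12.87 (ng/dL to pmol/L) and
#' 1.536 (pg/mL to pmol/L). Empty cells and the literal "NA" become missing
#' values; no sentinel numerics are ever interpreted.
#'
#' @param path Path to a delimited text file with a header row.
#' @param unit_dialect `"SI_pmol"` (the default; concentrations already in
#'   SI units) or `"conventional_ngdl_pgml"`.
#' @param aliases Optional named character vector mapping canonical column
#'   names to the header names actually present, e.g.
#'   `c(tsh = "TSH_mIU_L")`. Typically supplied via [read_config()].
#' @param limits Plausibility windows per analyte as a named list of
#'   `c(low, high)` pairs; values outside their window (including negative
#'   concentrations) are a hard error.
#'
#' @return A tibble of class `thyro_cohort` with canonical columns, one row
#'   per patient; provenance (source path, dialect, row count) stored in the
#'   `"provenance"` attribute.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(n_total = 20, n_panel = 15, n_full_panel = 10,
#'                              seed = 1), path)
#' cohort <- read_cohort(path)
read_cohort <- function(path, unit_dialect = c("SI_pmol", "conventional_ngdl_pgml"),
                        aliases = NULL, limits = default_plausibility()) {
  unit_dialect <- match.arg(unit_dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (!is.null(aliases) && length(aliases) > 0) {
    for (canon in names(aliases)) {
      if (aliases[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == aliases[[canon]]] <- canon
      }
    }
  }
  unknown <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(unknown) > 0) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  missing_cols <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(COHORT_COLUMNS, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, COHORT_COLUMNS]

  numeric_cols <- c("tsh", "ft4", "ft3", "age", "creatinine", "initial_ef",
                    "followup_days")
  for (col in numeric_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("unparseable numeric cell at row %d, column '%s': \"%s\"",
                   bad[1], col, vals[bad[1]]), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  for (col in COHORT_FLAGS) raw[[col]] <- parse_flag(raw[[col]], col)
  raw$sex <- parse_level(raw$sex, c("female", "male"), "sex")
  raw$ballooning <- parse_level(raw$ballooning, BALLOONING_LEVELS, "ballooning")

  if (unit_dialect == "conventional_ngdl_pgml") {
    raw$ft4 <- raw$ft4 * FT4_NGDL_TO_PMOLL
    raw$ft3 <- raw$ft3 * FT3_PGML_TO_PMOLL
  }

  cohort <- tibble::as_tibble(raw)
  validate_cohort(cohort, limits = limits)
  attr(cohort, "provenance") <- list(
    source = path, unit_dialect = unit_dialect, n_rows = nrow(cohort)
  )
  class(cohort) <- c("thyro_cohort", class(cohort))
  cohort
}

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("unparseable flag at row %d, column '%s': \"%s\"",
                 bad[1], col, x[bad[1]]), call. = FALSE)
  }
  as.logical(out)
}

parse_level <- function(x, levels, col) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    stop(sprintf("invalid value at row %d, column '%s': \"%s\" (expected %s)",
                 bad[1], col, x[bad[1]], paste(levels, collapse = "/")),
         call. = FALSE)
  }
  x
}

#' Validate a cohort table
#'
#' Enforces the record invariants every downstream stage relies on: unique
#' patient identifiers, non-negative follow-up times, binary outcome where
#' follow-up is recorded, and analyte values inside their plausibility
#' windows.
#'
#' @param cohort A cohort tibble.
#' @param limits Plausibility windows (see [read_cohort()]).
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, limits = default_plausibility()) {
  stopifnot(is.data.frame(cohort))
  ids <- cohort$patient_id
  if (anyNA(ids)) stop("patient_id must not be missing", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate patient_id: ", dup, call. = FALSE)
  }
  fu <- cohort$followup_days
  if (any(!is.na(fu) & fu < 0)) stop("followup_days must be >= 0", call. = FALSE)
  for (col in names(limits)) {
    v <- cohort[[col]]
    if (is.null(v)) next
    win <- limits[[col]]
    bad <- which(!is.na(v) & (v < win[1] | v > win[2]))
    if (length(bad) > 0) {
      stop(sprintf("implausible %s at row %d: %g (allowed %g-%g)",
                   col, bad[1], v[bad[1]], win[1], win[2]), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Round-trip companion of [read_cohort()]: all non-missing values are
#' written to full precision and missing values as empty cells, so that
#' reading the file back reproduces the table exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, intersect(COHORT_COLUMNS, names(cohort))]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Filter a cohort to the records eligible for an analysis stage
#'
#' The registry flow keeps different subsets per stage: the cluster analysis
#' needs TSH and FT4, the survival analysis needs outcome data, and the
#' full-panel analyses (SPINA-GD, FT3 comparisons) additionally need FT3.
#'
#' @param cohort A cohort tibble.
#' @param stage `"cluster"`, `"survival"` or `"full_panel"`.
#' @return The filtered tibble; before/after counts are recorded in the
#'   `"flow"` attribute and reported via `message()`. An empty result is a
#'   warning, not an error.
#' @export
eligibility_filter <- function(cohort, stage = c("cluster", "survival", "full_panel")) {
  stage <- match.arg(stage)
  keep <- switch(stage,
    cluster    = !is.na(cohort$tsh) & !is.na(cohort$ft4),
    survival   = !is.na(cohort$died) & !is.na(cohort$followup_days),
    full_panel = !is.na(cohort$tsh) & !is.na(cohort$ft4) & !is.na(cohort$ft3)
  )
  out <- cohort[keep, , drop = FALSE]
  message(sprintf("eligibility [%s]: kept %d of %d records", stage, nrow(out),
                  nrow(cohort)))
  if (nrow(out) == 0) warning("no records eligible for stage '", stage, "'",
                              call. = FALSE)
  attr(out, "flow") <- list(stage = stage, before = nrow(cohort), after = nrow(out))
  out
}

#' Stage counts of a cohort (screening flow)
#'
#' Mirrors the screening flow chart: how many records were screened and how
#' many are eligible for each analysis stage.
#'
#' @param cohort A cohort tibble.
#' @return A one-row tibble with `n_screened`, `n_cluster` (TSH+FT4
#'   present), `n_full_panel` (TSH+FT4+FT3), `n_survival` (outcome present)
#'   and `n_cluster_survival` (both).
#' @export
cohort_flow <- function(cohort) {
  has_panel <- !is.na(cohort$tsh) & !is.na(cohort$ft4)
  has_ft3 <- has_panel & !is.na(cohort$ft3)
  has_outcome <- !is.na(cohort$died) & !is.na(cohort$followup_days)
  tibble::tibble(
    n_screened = nrow(cohort),
    n_cluster = sum(has_panel),
    n_full_panel = sum(has_ft3),
    n_survival = sum(has_outcome),
    n_cluster_survival = sum(has_panel & has_outcome)
  )
}

#' Write the screening-flow summary as JSON
#'
#' @param cohort A cohort tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_flow_json <- function(cohort, path) {
  jsonlite::write_json(as.list(cohort_flow(cohort)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
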