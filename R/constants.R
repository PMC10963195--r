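#' Structure-parameter constants for thyroid homeostasis calculations
#'
#' Kinetic and binding constants of the hypothalamus-pituitary-thyroid
#' feedback model that underlie the calculated structure parameters
#' SPINA-GT (thyroid's secretory capacity) and SPINA-GD (sum activity of
#' peripheral step-up deiodinases), plus the FT4 upper reference limit used
#' by the thyrotroph thyroid hormone resistance index (TTSI).
#'
#' Defaults follow the published SPINA parameterization. All concentrations
#' are handled internally in molar units; the user-facing panel stays in the
#' clinical units TSH mIU/L, FT4 pmol/L, FT3 pmol/L.
#'
#' @param ... Named overrides for individual constants, e.g.
#'   `spina_constants(ft4_upper_ref = 20)`.
#'
#' @return A named list of class `spina_constants`:
#' \describe{
#'   \item{alpha_T}{Dilution factor for T4 (1/L).}
#'   \item{beta_T}{Clearance exponent for T4 (1/s).}
#'   \item{D_T}{EC50 of TSH at the thyroid (mIU/L).}
#'   \item{K41}{Association constant T4--TBG (L/mol).}
#'   \item{K42}{Association constant T4--transthyretin (L/mol).}
#'   \item{TBG}{Thyroxine-binding globulin concentration (mol/L).}
#'   \item{TTR_sub}{Transthyretin-class binder concentration (mol/L).}
#'   \item{alpha_31}{Dilution factor for T3 (1/L).}
#'   \item{beta_31}{Clearance exponent for T3 (1/s).}
#'   \item{K_M1}{Michaelis constant of type-1 deiodinase (mol/L).}
#'   \item{K30}{Association constant T3--TBG (L/mol).}
#'   \item{ft4_upper_ref}{Upper FT4 reference limit (pmol/L) for TTSI.}
#' }
#' @export
#' @examples
#' k <- spina_constants()
#' spina_gt(tsh = 1.0, ft4 = 14.1, constants = k)
spina_constants <- function(...) {
  defaults <- list(
    alpha_T       = 0.1,      # 1/L
    beta_T        = 1.1e-6,   # 1/s
    D_T           = 2.75,     # mIU/L
    K41           = 2e10,     # L/mol
    K42           = 2e8,      # L/mol
    TBG           = 3e-7,     # mol/L (300 nmol/L)
    TTR_sub       = 4.5e-6,   # mol/L
    alpha_31      = 0.026,    # 1/L
    beta_31       = 8e-6,     # 1/s
    K_M1          = 5e-7,     # mol/L (500 nmol/L)
    K30           = 2e9,      # L/mol
    ft4_upper_ref = 22        # pmol/L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- utils::modifyList(defaults, overrides)
  bad <- names(out)[!vapply(out, function(v) is.numeric(v) && length(v) == 1 && v > 0, logical(1))]
  if (length(bad) > 0) {
    stop("constants must be single positive numbers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(out, class = "spina_constants")
}

#' Laboratory reference ranges for the thyroid panel
#'
#' The ranges that drive endotype classification. Assay-specific ranges vary
#' across laboratories; these defaults are widely used assay ranges and are
#' fully configurable (and echoed into reports so every result records the
#' ranges it was computed under).
#'
#' @param tsh_low,tsh_high TSH range, mIU/L.
#' @param ft4_low,ft4_high Free T4 range, pmol/L.
#' @param ft3_low,ft3_high Free T3 range, pmol/L.
#'
#' @return A named list of class `reference_ranges`.
#' @export
reference_ranges <- function(tsh_low = 0.4, tsh_high = 4.0,
                             ft4_low = 10, ft4_high = 23,
                             ft3_low = 3.1, ft3_high = 6.8) {
  out <- list(
    tsh_low = tsh_low, tsh_high = tsh_high,
    ft4_low = ft4_low, ft4_high = ft4_high,
    ft3_low = ft3_low, ft3_high = ft3_high
  )
  for (an in c("tsh", "ft4", "ft3")) {
    if (out[[paste0(an, "_low")]] >= out[[paste0(an, "_high")]]) {
      stop("reference range for ", an, " must have low < high", call. = FALSE)
    }
  }
  structure(out, class = "reference_ranges")
}

#' Read analysis configuration (constants, ranges, column aliases) from YAML
#'
#' The YAML file may contain top-level blocks `constants`, `ranges` and
#' `aliases`; each is optional and merged over the package defaults. The
#' `aliases` block maps canonical column names to the header names used by a
#' registry export, e.g. `tsh: "TSH_mIU_L"`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `constants` (`spina_constants`), `ranges`
#'   (`reference_ranges`) and `aliases` (named character vector, possibly
#'   empty).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  constants <- do.call(spina_constants, as.list(raw$constants %||% list()))
  ranges <- do.call(reference_ranges, as.list(raw$ranges %||% list()))
  aliases <- unlist(raw$aliases %||% list())
  list(constants = constants, ranges = ranges, aliases = aliases)
}

#' Serialize a configuration for provenance
#'
#' Every results report echoes the constants and ranges it was produced
#' under; this helper renders them as a plain list suitable for
#' `jsonlite::write_json()` or `yaml::write_yaml()`.
#'
#' @param constants A `spina_constants` object.
#' @param ranges A `reference_ranges` object.
#' @return A plain named list.
#' @export
config_provenance <- function(constants = spina_constants(),
                              ranges = reference_ranges()) {
  list(constants = unclass(constants), ranges = unclass(ranges))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
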