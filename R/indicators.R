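#' Treatment codes of the fertilization trial
#'
#' The five fertilization regimes of the trial design: an unfertilized
#' control (CK), chemical fertilizer only (CF), and three blends replacing
#' 25/50/75 percent of the chemical nitrogen with organic fertilizer
#' (M1/M2/M3). The organic fraction is determined by the code.
#'
#' @return A data frame with columns `treatment` and `organic_fraction`.
#' @export
#' @examples
#' treatment_codes()
treatment_codes <- function() {
  data.frame(
    treatment        = c("CK", "CF", "M1", "M2", "M3"),
    organic_fraction = c(0, 0, 0.25, 0.50, 0.75),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
treatment_levels <- function() treatment_codes()$treatment

#' Coerce and validate treatment labels
#'
#' @param x Character vector of treatment codes.
#' @return A factor with levels CK, CF, M1, M2, M3.
#' @export
as_treatment <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), treatment_levels())
  if (length(bad) > 0) {
    sq_validation_error(sprintf(
      "unknown treatment code(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(treatment_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = treatment_levels())
}

#' Metadata for the twelve soil indicators
#'
#' Canonical names, units and scoring directions for the final-year soil
#' panel: bulk density, pH, organic matter, total N, ammonium N, nitrate N,
#' alkali-hydrolyzable N, available P, available K, and the urease, catalase
#' and alkaline-phosphatase enzyme activities.
#'
#' Scoring direction encodes how an indicator relates to soil function:
#' `more_is_better` indicators are scored increasing in the raw value,
#' `less_is_better` decreasing. By default bulk density and pH are
#' `less_is_better` (compaction and alkalinity both impair function on
#' these calcareous soils) and the ten nutrient/enzyme indicators are
#' `more_is_better`; the direction map is an argument everywhere it is
#' used, so pH in particular can be reassigned.
#'
#' @param direction_overrides Named character vector, e.g.
#'   `c(ph = "more_is_better")`, replacing default directions.
#' @return Data frame with columns `indicator`, `unit`, `direction`.
#' @export
#' @examples
#' soil_indicators()
#' soil_indicators(c(ph = "more_is_better"))
soil_indicators <- function(direction_overrides = NULL) {
  meta <- data.frame(
    indicator = c("bd", "ph", "som", "tn", "nh4_n", "no3_n",
                  "alkali_n", "ap", "ak", "ur", "cat", "alp"),
    unit = c("g/cm3", "unitless", "g/kg", "g/kg", "mg/kg", "mg/kg",
             "mg/kg", "mg/kg", "mg/kg", "activity", "activity", "activity"),
    direction = c("less_is_better", "less_is_better", rep("more_is_better", 10)),
    stringsAsFactors = FALSE
  )
  if (!is.null(direction_overrides)) {
    nm <- names(direction_overrides)
    bad <- setdiff(nm, meta$indicator)
    if (length(bad) > 0) {
      sq_config_error(sprintf("direction override for unknown indicator(s): %s",
                              paste(bad, collapse = ", ")))
    }
    ok <- direction_overrides %in% c("more_is_better", "less_is_better")
    if (!all(ok)) sq_config_error("directions must be 'more_is_better' or 'less_is_better'")
    meta$direction[match(nm, meta$indicator)] <- unname(direction_overrides)
  }
  meta
}

#' @keywords internal
indicator_names <- function() soil_indicators()$indicator

#' Indicator alias table
#'
#' Maps the column headers found in third-party tables (the abbreviations
#' used in figures, chemical notations, spelled-out names) onto the twelve
#' canonical indicator names, so external tables load without renaming.
#'
#' @return Data frame with columns `alias` and `indicator`.
#' @export
indicator_aliases <- function() {
  al <- list(
    bd       = c("bd", "BD", "bulk_density", "soil_bulk_density"),
    ph       = c("ph", "pH", "PH", "soil_ph"),
    som      = c("som", "SOM", "organic_matter", "soil_organic_matter", "om"),
    tn       = c("tn", "TN", "total_n", "total_nitrogen"),
    nh4_n    = c("nh4_n", "NH4-N", "NH4_N", "nh4n", "ammonium_n", "ammonium_nitrogen"),
    no3_n    = c("no3_n", "NO3-N", "NO3_N", "no3n", "nitrate_n", "nitrate_nitrogen"),
    alkali_n = c("alkali_n", "Alkali-N", "Alkali_N", "AN", "alkali_hydrolyzable_n",
                 "alkaline_hydrolysable_n", "available_n"),
    ap       = c("ap", "AP", "available_p", "available_phosphorus"),
    ak       = c("ak", "AK", "available_k", "available_potassium"),
    ur       = c("ur", "Ur", "UR", "urease", "urease_activity"),
    cat      = c("cat", "CAT", "Cat", "catalase", "catalase_activity"),
    alp      = c("alp", "ALP", "Alp", "alkaline_phosphatase", "akp")
  )
  data.frame(
    alias = unlist(al, use.names = FALSE),
    indicator = rep(names(al), lengths(al)),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
#' Map raw column names to canonical indicator names; non-indicator names
#' pass through unchanged.
canonicalize_names <- function(nms) {
  tab <- indicator_aliases()
  hit <- match(nms, tab$alias)
  ifelse(is.na(hit), nms, tab$indicator[hit])
}
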