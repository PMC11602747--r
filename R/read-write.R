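#' @keywords internal
#' Parse a character column to numeric, reporting offending data lines
#' (1-based, header = line 1) instead of silently producing NA.
parse_numeric_column <- function(x, column, permissive = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "" & toupper(trimws(x)) != "NA")
  if (length(bad) > 0) {
    sq_validation_error(sprintf(
      "column '%s': unparseable number '%s' at data line %d (file line %d)",
      column, x[bad[1]], bad[1], bad[1] + 1L
    ))
  }
  if (any(is.na(out)) && !permissive) {
    sq_validation_error(sprintf(
      "column '%s': missing value at data line %d; rerun with permissive = TRUE to tag missing rows",
      column, which(is.na(out))[1]
    ))
  }
  out
}

#' Read a long-format yield table
#'
#' Reads a CSV with one row per plot-year: columns `plot_id`, `block`,
#' `treatment`, `year`, `yield` (seed-cotton yield, kg/ha). Decimal
#' separator is always "." regardless of locale. Row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param permissive If `FALSE` (default) missing values are an error; if
#'   `TRUE` rows with missing yields are kept and flagged in an
#'   `incomplete` attribute for listwise deletion downstream.
#' @return A data frame of validated yield records.
#' @export
read_yield_table <- function(path, permissive = FALSE) {
  if (!file.exists(path)) sq_schema_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- trimws(names(raw))
  need <- c("plot_id", "block", "treatment", "year", "yield")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    sq_schema_error(sprintf("yield table %s is missing required column(s): %s",
                            path, paste(miss, collapse = ", ")))
  }
  out <- data.frame(
    plot_id   = raw$plot_id,
    block     = as.integer(parse_numeric_column(raw$block, "block")),
    treatment = as_treatment(raw$treatment),
    year      = as.integer(parse_numeric_column(raw$year, "year")),
    yield     = parse_numeric_column(raw$yield, "yield", permissive = permissive),
    stringsAsFactors = FALSE
  )
  neg <- which(out$yield < 0)
  if (length(neg) > 0) {
    sq_validation_error(sprintf("negative yield (%g) for plot '%s', year %d",
                                out$yield[neg[1]], out$plot_id[neg[1]], out$year[neg[1]]))
  }
  dup <- duplicated(out[c("plot_id", "year")])
  if (any(dup)) {
    sq_validation_error(sprintf("duplicate (plot_id, year) key: ('%s', %d)",
                                out$plot_id[which(dup)[1]], out$year[which(dup)[1]]))
  }
  attr(out, "incomplete") <- which(is.na(out$yield))
  out
}

#' Read a plot-level soil indicator table
#'
#' Reads a CSV with one row per plot: `plot_id`, `treatment`, and the twelve
#' soil indicator columns. Headers are matched through the documented alias
#' table (`indicator_aliases()`), so `"NO3-N"`, `"nitrate_n"` and `"no3_n"`
#' all load as the same indicator.
#'
#' @inheritParams read_yield_table
#' @return A data frame with `plot_id`, `treatment` and the twelve canonical
#'   indicator columns.
#' @export
read_soil_table <- function(path, permissive = FALSE) {
  if (!file.exists(path)) sq_schema_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- canonicalize_names(trimws(names(raw)))
  miss <- setdiff(c("plot_id", "treatment", indicator_names()), names(raw))
  if (length(miss) > 0) {
    sq_schema_error(sprintf("soil table %s is missing required column(s): %s",
                            path, paste(miss, collapse = ", ")))
  }
  out <- data.frame(plot_id = raw$plot_id,
                    treatment = as_treatment(raw$treatment),
                    stringsAsFactors = FALSE)
  for (ind in indicator_names()) {
    out[[ind]] <- parse_numeric_column(raw[[ind]], ind, permissive = permissive)
  }
  validate_soil_values(out)
  dup <- duplicated(out$plot_id)
  if (any(dup)) {
    sq_validation_error(sprintf("duplicate plot_id: '%s'", out$plot_id[which(dup)[1]]))
  }
  out
}

#' @keywords internal
validate_soil_values <- function(soil) {
  check <- function(cond, ind, what) {
    bad <- which(!cond & !is.na(cond))
    if (length(bad) > 0) {
      sq_validation_error(sprintf("indicator '%s' %s for plot '%s' (value %g)",
                                  ind, what, soil$plot_id[bad[1]], soil[[ind]][bad[1]]))
    }
  }
  check(soil$bd > 0, "bd", "must be > 0")
  check(soil$ph > 0 & soil$ph < 14, "ph", "must lie in (0, 14)")
  for (ind in setdiff(indicator_names(), c("bd", "ph"))) {
    check(soil[[ind]] >= 0, ind, "must be >= 0")
  }
  invisible(soil)
}

#' Write yield / soil tables at full precision
#'
#' Numeric values are written with 17 significant digits so that a write
#' followed by a read reproduces the records exactly.
#'
#' @param x Data frame from [read_yield_table()]/[simulate_yields()] (or the
#'   soil analogue).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(x, path) {
  out <- x
  out$yield <- sprintf("%.17g", x$yield)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_yield_table
#' @export
write_soil_table <- function(x, path) {
  out <- x
  for (ind in intersect(indicator_names(), names(out))) {
    out[[ind]] <- sprintf("%.17g", x[[ind]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a trial table against an expected design
#'
#' Compares loaded yield and soil tables with an expected randomized-block
#' layout and reports every violation: unknown or unbalanced treatments,
#' missing plot-years, duplicate keys, and soil plots without yield series.
#' Always returns a report (never throws); an empty report means the tables
#' match the design.
#'
#' @param yields Yield records (may be `NULL`).
#' @param soil Soil indicator records (may be `NULL`).
#' @param expected List with `n_treatments`, `n_blocks`, `n_years`.
#' @return A data frame with columns `type` and `detail`; zero rows when the
#'   design is satisfied.
#' @export
validate_design <- function(yields = NULL, soil = NULL,
                            expected = list(n_treatments = 5, n_blocks = 6, n_years = 10)) {
  if (is.null(yields) && is.null(soil)) sq_data_error("nothing to validate")
  issues <- list()
  note <- function(type, detail) issues[[length(issues) + 1]] <<- data.frame(
    type = type, detail = detail, stringsAsFactors = FALSE)

  if (!is.null(yields)) {
    dup <- duplicated(yields[c("plot_id", "year")])
    for (i in which(dup)) {
      note("duplicate_key", sprintf("duplicate (plot_id, year) = ('%s', %d)",
                                    yields$plot_id[i], yields$year[i]))
    }
    tr <- unique(as.character(yields$treatment))
    if (length(tr) != expected$n_treatments) {
      note("treatment_count", sprintf("expected %d treatments, found %d",
                                      expected$n_treatments, length(tr)))
    }
    plots_per_tr <- tapply(yields$plot_id, as.character(yields$treatment),
                           function(p) length(unique(p)))
    if (length(unique(plots_per_tr)) > 1) {
      note("unbalanced", sprintf("plots per treatment differ: %s",
                                 paste(sprintf("%s=%d", names(plots_per_tr), plots_per_tr),
                                       collapse = ", ")))
    }
    if (any(plots_per_tr != expected$n_blocks)) {
      off <- names(plots_per_tr)[plots_per_tr != expected$n_blocks]
      note("block_count", sprintf("treatment(s) %s do not have %d replicate plots",
                                  paste(off, collapse = ", "), expected$n_blocks))
    }
    all_years <- sort(unique(yields$year))
    if (length(all_years) != expected$n_years) {
      note("year_count", sprintf("expected %d years, found %d",
                                 expected$n_years, length(all_years)))
    }
    for (p in unique(yields$plot_id)) {
      have <- yields$year[yields$plot_id == p]
      missing <- setdiff(all_years, have)
      for (y in missing) {
        note("missing_plot_year", sprintf("plot '%s' has no record for year %d", p, y))
      }
    }
  }
  if (!is.null(soil)) {
    dup <- duplicated(soil$plot_id)
    for (i in which(dup)) note("duplicate_key", sprintf("duplicate plot_id '%s'", soil$plot_id[i]))
    if (!is.null(yields)) {
      orphan <- setdiff(unique(soil$plot_id), unique(yields$plot_id))
      for (p in orphan) note("soil_without_yield", sprintf("soil plot '%s' has no yield records", p))
    }
    per_tr <- table(as.character(soil$treatment))
    if (any(per_tr != expected$n_blocks)) {
      off <- names(per_tr)[per_tr != expected$n_blocks]
      note("block_count", sprintf("soil table: treatment(s) %s do not have %d plots",
                                  paste(off, collapse = ", "), expected$n_blocks))
    }
  }
  if (length(issues) == 0) {
    data.frame(type = character(0), detail = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' @keywords internal
#' Canonical in-memory ordering of yield records: (treatment, block, year).
canonical_order <- function(yields) {
  yields[order(yields$treatment, yields$block, yields$year), , drop = FALSE]
}
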