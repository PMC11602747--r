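#' Sustainable yield index of a multi-year series
#'
#' `SYI = (Ymean - sigma) / Ymax`: the mean yield minus its standard
#' deviation, relative to the highest yield of the series. SYI is at most 1,
#' equals 1 only for a constant positive series, and can be negative when
#' the dispersion exceeds the mean (such values are returned as-is with a
#' warning, not clipped). The index is invariant to rescaling the series by
#' any positive constant.
#'
#' @param y Numeric vector of yields (>= 2 values, all nonnegative, max > 0).
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @param details If `TRUE` return a list with the components (`mean`,
#'   `sd`, `max`, `syi`) for audit; otherwise the SYI value.
#' @return Numeric SYI, or a list when `details = TRUE`.
#' @export
#' @examples
#' syi(c(4, 6))            # (5 - sqrt(2)) / 6
#' syi(rep(1200, 10))      # constant series: exactly 1
syi <- function(y, sd_mode = c("sample", "population"), details = FALSE) {
  sd_mode <- match.arg(sd_mode)
  if (length(y) < 2) sq_data_error("SYI needs at least 2 years of yields")
  if (any(is.na(y))) sq_data_error("SYI input contains missing values")
  if (any(y < 0)) sq_data_error("yields must be nonnegative")
  ymax <- max(y)
  if (ymax <= 0) sq_data_error("all-zero series: SYI undefined (division by zero)")
  s <- stats::sd(y)
  if (sd_mode == "population") s <- s * sqrt((length(y) - 1) / length(y))
  val <- (mean(y) - s) / ymax
  if (val < 0) warning(sprintf("negative SYI (%.4f): dispersion exceeds mean yield", val),
                       call. = FALSE)
  if (details) list(syi = val, mean = mean(y), sd = s, max = ymax, sd_mode = sd_mode)
  else val
}

#' Per-plot mean yield and sustainability of a trial
#'
#' Computes, for every plot, the mean annual yield and the sustainable yield
#' index over the plot's own year series, then aggregates both by treatment
#' (mean and standard error across the replicate plots). The replicate-level
#' values are retained so the indices can be fed to ANOVA and the letter
#' display exactly like any measured response.
#'
#' @param yields Long-format yield records (`plot_id`, `treatment`, `year`,
#'   `yield`).
#' @param sd_mode Standard-deviation convention passed to [syi()].
#' @return Object of class `yield_sustainability` with `plot` (per-plot
#'   `mean_yield` and `syi`) and `treatment` (per-treatment summaries).
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 1))
#' ys <- yield_sustainability(trial$yields)
#' ys
yield_sustainability <- function(yields, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  need <- c("plot_id", "treatment", "year", "yield")
  if (!all(need %in% names(yields))) {
    sq_schema_error("yield table needs columns plot_id, treatment, year, yield")
  }
  yields <- yields[order(yields$plot_id, yields$year), ]
  ids <- unique(yields$plot_id)
  rows <- lapply(ids, function(p) {
    sub <- yields[yields$plot_id == p, ]
    if (anyDuplicated(sub$year)) {
      sq_validation_error(sprintf("plot '%s' has duplicated years", p))
    }
    val <- tryCatch(
      syi(sub$yield, sd_mode = sd_mode),
      soilqi_error = function(e) {
        sq_data_error(sprintf("plot '%s': %s", p, conditionMessage(e)))
      }
    )
    data.frame(plot_id = p, treatment = as.character(sub$treatment[1]),
               mean_yield = mean(sub$yield), syi = val,
               stringsAsFactors = FALSE)
  })
  plot_df <- do.call(rbind, rows)
  plot_df$treatment <- as_treatment(plot_df$treatment)
  tr <- merge(group_mean_se(plot_df$mean_yield, plot_df$treatment, "yield"),
              group_mean_se(plot_df$syi, plot_df$treatment, "syi"),
              by = "treatment")
  tr <- tr[order(match(tr$treatment, treatment_levels())), ]
  rownames(tr) <- NULL
  structure(list(plot = plot_df, treatment = tr[, c("treatment", "yield_mean",
                                                    "yield_se", "syi_mean", "syi_se",
                                                    "n.x")],
                 sd_mode = sd_mode),
            class = "yield_sustainability")
}

#' @export
print.yield_sustainability <- function(x, digits = 4, ...) {
  cat(sprintf("Yield sustainability (%d plots, sd_mode = %s)\n",
              nrow(x$plot), x$sd_mode))
  out <- x$treatment
  names(out)[names(out) == "n.x"] <- "n"
  out$yield_mean <- round(out$yield_mean, 1)
  out$yield_se <- round(out$yield_se, 1)
  out$syi_mean <- round(out$syi_mean, digits)
  out$syi_se <- round(out$syi_se, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
plot.yield_sustainability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$treatment$yield_mean, names.arg = x$treatment$treatment,
                    ylab = "Mean yield (kg/ha)")
  graphics::barplot(x$treatment$syi_mean, names.arg = x$treatment$treatment,
                    ylab = "Sustainable yield index", ylim = c(0, 1))
  invisible(x)
}

#' Per-plot and per-treatment mean annual yield
#'
#' @param yields Long-format yield records.
#' @return List with `plot` (per-plot means) and `treatment` (mean, SE, n).
#' @export
mean_annual_yield <- function(yields) {
  need <- c("plot_id", "treatment", "year", "yield")
  if (!all(need %in% names(yields))) {
    sq_schema_error("yield table needs columns plot_id, treatment, year, yield")
  }
  if (nrow(yields) == 0) sq_data_error("empty yield table")
  ids <- unique(yields$plot_id)
  rows <- lapply(ids, function(p) {
    sub <- yields[yields$plot_id == p, ]
    data.frame(plot_id = p, treatment = as.character(sub$treatment[1]),
               mean_yield = mean(sub$yield), stringsAsFactors = FALSE)
  })
  plot_df <- do.call(rbind, rows)
  plot_df$treatment <- as_treatment(plot_df$treatment)
  list(plot = plot_df,
       treatment = group_mean_se(plot_df$mean_yield, plot_df$treatment, "yield"))
}
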