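#' Direction-aware min-max scoring of soil indicators
#'
#' Converts each indicator to a score in [0, 1]. For a "more is better"
#' indicator the score is `(x - xmin) / (xmax - xmin)`; for "less is better"
#' it is `(xmax - x) / (xmax - xmin)`. Bounds default to the observed
#' minimum and maximum over all plots jointly (one shared ruler across
#' treatments); fixed bounds can be supplied instead, in which case scores
#' are clipped into [0, 1].
#'
#' @param soil Data frame with `plot_id`, `treatment` and indicator columns.
#' @param meta Indicator metadata from [soil_indicators()]; its `direction`
#'   column decides the scoring formula per indicator.
#' @param bounds Optional data frame with columns `indicator`, `xmin`,
#'   `xmax` fixing the scoring bounds.
#' @param on_degenerate What to do when data-derived bounds collapse
#'   (`xmax == xmin`): `"error"` (default) or `"drop"` the indicator with a
#'   warning.
#' @return An object of class `score_matrix`: list with `scores` (plots x
#'   indicators matrix), `plot_id`, `treatment`, `bounds` (the bounds
#'   actually applied, with their provenance) and `direction`.
#' @export
#' @examples
#' soil <- simulate_trial(trial_config(seed = 1))$soil
#' sc <- score_indicators(soil)
#' range(sc$scores)
score_indicators <- function(soil, meta = soil_indicators(), bounds = NULL,
                             on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  inds <- intersect(meta$indicator, names(soil))
  if (length(inds) == 0) sq_data_error("no indicator columns found in table")
  dir <- stats::setNames(meta$direction[match(inds, meta$indicator)], inds)

  fixed <- !is.null(bounds)
  if (fixed) {
    miss <- setdiff(inds, bounds$indicator)
    if (length(miss) > 0) {
      sq_config_error(sprintf("fixed bounds missing indicator(s): %s",
                              paste(miss, collapse = ", ")))
    }
  }
  scores <- matrix(NA_real_, nrow(soil), length(inds),
                   dimnames = list(soil$plot_id, inds))
  keep <- character(0)
  brows <- list()
  for (ind in inds) {
    x <- soil[[ind]]
    if (fixed) {
      b <- bounds[bounds$indicator == ind, ]
      lo <- b$xmin[1]; hi <- b$xmax[1]; src <- "fixed"
    } else {
      lo <- min(x); hi <- max(x); src <- "data"
    }
    if (hi <= lo) {
      if (on_degenerate == "drop") {
        warning(sprintf("indicator '%s' has degenerate bounds (xmin == xmax); dropped", ind),
                call. = FALSE)
        next
      }
      sq_data_error(sprintf("indicator '%s' has degenerate bounds (xmin == xmax == %g)", ind, lo))
    }
    s <- if (dir[[ind]] == "more_is_better") (x - lo) / (hi - lo) else (hi - x) / (hi - lo)
    scores[, ind] <- pmin(pmax(s, 0), 1)
    keep <- c(keep, ind)
    brows[[ind]] <- data.frame(indicator = ind, xmin = lo, xmax = hi,
                               direction = dir[[ind]], source = src,
                               stringsAsFactors = FALSE)
  }
  if (length(keep) == 0) sq_data_error("all indicators degenerate; nothing to score")
  structure(
    list(scores = scores[, keep, drop = FALSE],
         plot_id = soil$plot_id,
         treatment = soil$treatment,
         bounds = do.call(rbind, brows[keep]),
         direction = dir[keep]),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Indicator score matrix: %d plots x %d indicators (all scores in [0,1])\n",
              nrow(x$scores), ncol(x$scores)))
  cat("Bounds source:", paste(unique(x$bounds$source), collapse = "/"), "\n")
  print(utils::head(round(x$scores, 3)))
  invisible(x)
}
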