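#' Composite soil quality index from scores and weights
#'
#' The soil quality index of a plot is the weighted sum of its indicator
#' scores, `SQI = sum_i W_i * S_i`, with the communality-ratio weights.
#' Because scores lie in [0, 1] and weights sum to one, every SQI lies in
#' [0, 1]; higher values indicate superior soil function.
#'
#' @param scores A `score_matrix` from [score_indicators()].
#' @param weights A `weight_vector` from [weights_from_communalities()] (or
#'   a named numeric vector of weights summing to 1).
#' @return Object of class `sqi_result`: `plot` data frame (`plot_id`,
#'   `treatment`, `sqi`) and `treatment` summary (`mean`, `se`, `n`).
#' @export
compute_sqi <- function(scores, weights) {
  stopifnot(inherits(scores, "score_matrix"))
  w <- if (inherits(weights, "weight_vector")) weights$weights else weights
  if (is.null(names(w))) sq_data_error("weights must be named by indicator")
  sym_diff <- c(setdiff(colnames(scores$scores), names(w)),
                setdiff(names(w), colnames(scores$scores)))
  if (length(sym_diff) > 0) {
    sq_data_error(sprintf("score/weight indicator mismatch: %s",
                          paste(unique(sym_diff), collapse = ", ")))
  }
  w <- w[colnames(scores$scores)]
  sqi <- as.numeric(scores$scores %*% w)
  plot_df <- data.frame(plot_id = scores$plot_id, treatment = scores$treatment,
                        sqi = sqi, stringsAsFactors = FALSE)
  structure(
    list(plot = plot_df,
         treatment = group_mean_se(plot_df$sqi, plot_df$treatment, "sqi"),
         weights = w),
    class = "sqi_result"
  )
}

#' @keywords internal
group_mean_se <- function(values, groups, name = "value") {
  g <- factor(groups)
  m <- tapply(values, g, mean)
  s <- tapply(values, g, function(v) stats::sd(v) / sqrt(length(v)))
  n <- tapply(values, g, length)
  out <- data.frame(treatment = names(m), mean = as.numeric(m),
                    se = as.numeric(s), n = as.integer(n),
                    stringsAsFactors = FALSE)
  names(out)[2] <- paste0(name, "_mean")
  names(out)[3] <- paste0(name, "_se")
  out
}

#' Fit the composite soil-quality model
#'
#' The one-call interface to the index: scores the indicators
#' (direction-aware min-max), extracts principal-component communalities
#' from the standardized indicators, forms communality-ratio weights, and
#' computes each plot's soil quality index. Returns a classed object with
#' the usual accessors (`coef` gives the weights, `fitted` the per-plot
#' index, `predict` scores new plots on the stored bounds and weights).
#'
#' @param soil Soil indicator table (e.g. from [simulate_soil()] or
#'   [read_soil_table()]).
#' @param meta Indicator metadata; see [soil_indicators()].
#' @param bounds Optional fixed scoring bounds (see [score_indicators()]).
#' @param retention Component retention rule; see [pca_communalities()].
#' @param pca_on Extract communalities from the standardized raw values
#'   (`"raw"`, conventional, default) or from the min-max scores
#'   (`"scores"`).
#' @param ... Passed to [pca_communalities()] (`n_components`, `cum_var`).
#' @return Object of class `soil_quality` with elements `scores`,
#'   `communality`, `weights`, `sqi` (per-plot data frame), `treatment`
#'   (summary), and `call`.
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 1))
#' fit <- soil_quality(trial$soil)
#' fit
#' coef(fit)
soil_quality <- function(soil, meta = soil_indicators(), bounds = NULL,
                         retention = "kaiser", pca_on = c("raw", "scores"), ...) {
  pca_on <- match.arg(pca_on)
  sc <- score_indicators(soil, meta = meta, bounds = bounds)
  pca_input <- if (pca_on == "raw") {
    as.matrix(soil[, colnames(sc$scores), drop = FALSE])
  } else {
    sc$scores
  }
  comm <- pca_communalities(pca_input, retention = retention, ...)
  w <- weights_from_communalities(comm)
  res <- compute_sqi(sc, w)
  structure(
    list(scores = sc, communality = comm, weights = w,
         sqi = res$plot, treatment = res$treatment,
         meta = meta, pca_on = pca_on, call = match.call()),
    class = "soil_quality"
  )
}

#' @export
print.soil_quality <- function(x, digits = 4, ...) {
  cat("Soil quality index (weighted min-max scores, communality-ratio weights)\n")
  cat(sprintf("  %d plots, %d indicators, retention = %s, PCA on %s values\n",
              nrow(x$sqi), ncol(x$scores$scores), x$communality$retention, x$pca_on))
  cat("Per-treatment SQI:\n")
  print(transform(x$treatment,
                  sqi_mean = round(sqi_mean, digits),
                  sqi_se = round(sqi_se, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.soil_quality <- function(object, ...) {
  structure(list(
    treatment = object$treatment,
    weights = data.frame(indicator = names(object$weights$weights),
                         communality = unname(object$weights$communalities),
                         weight = unname(object$weights$weights),
                         stringsAsFactors = FALSE),
    eigenvalues = object$communality$eigenvalues,
    retained = object$communality$retained,
    bounds = object$scores$bounds
  ), class = "summary.soil_quality")
}

#' @export
print.summary.soil_quality <- function(x, digits = 4, ...) {
  cat("Indicator weights:\n")
  print(transform(x$weights, communality = round(communality, digits),
                  weight = round(weight, digits)), row.names = FALSE)
  cat(sprintf("\nEigenvalues (retained: %s):\n", paste(x$retained, collapse = ", ")))
  print(round(x$eigenvalues, digits))
  cat("\nPer-treatment SQI:\n")
  print(x$treatment, row.names = FALSE)
  invisible(x)
}

#' @export
coef.soil_quality <- function(object, ...) object$weights$weights

#' @export
fitted.soil_quality <- function(object, ...) {
  stats::setNames(object$sqi$sqi, object$sqi$plot_id)
}

#' Score new plots on a fitted soil-quality ruler
#'
#' Applies the stored scoring bounds, directions and weights to a new soil
#' table, so new plots are measured on the same ruler as the fitted ones.
#'
#' @param object A `soil_quality` fit.
#' @param newdata Soil indicator table.
#' @param ... Unused.
#' @return Named numeric vector of SQI values.
#' @export
predict.soil_quality <- function(object, newdata, ...) {
  sc <- score_indicators(newdata, meta = object$meta, bounds = object$scores$bounds)
  res <- compute_sqi(sc, object$weights)
  stats::setNames(res$plot$sqi, res$plot$plot_id)
}

#' @export
plot.soil_quality <- function(x, ...) {
  bp <- graphics::barplot(x$treatment$sqi_mean, names.arg = x$treatment$treatment,
                          ylab = "Soil quality index", ylim = c(0, 1), ...)
  graphics::arrows(bp, x$treatment$sqi_mean - x$treatment$sqi_se,
                   bp, x$treatment$sqi_mean + x$treatment$sqi_se,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}
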