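#' Configuration for random-forest permutation importance
#'
#' @param n_trees Trees per forest (>= 100; default 1000).
#' @param n_permutations Response permutations for the significance null
#'   (>= 99; default 99).
#' @param seed Integer seed; the observed fit uses `seed`, permutation b
#'   uses `seed + b`.
#' @return List of class `importance_config`.
#' @export
importance_config <- function(n_trees = 1000L, n_permutations = 99L, seed = 1L) {
  n_trees <- as.integer(n_trees); n_permutations <- as.integer(n_permutations)
  if (is.na(n_trees) || n_trees < 100) sq_config_error("n_trees must be >= 100")
  if (is.na(n_permutations) || n_permutations < 99) {
    sq_config_error("n_permutations must be >= 99")
  }
  structure(list(n_trees = n_trees, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "importance_config")
}

#' @keywords internal
rf_importance_once <- function(X, y, n_trees, seed) {
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  list(importance = randomForest::importance(rf, type = 1)[, 1],
       var_explained = 100 * rf$rsq[n_trees])
}

#' @keywords internal
check_importance_input <- function(predictors, response) {
  X <- as.data.frame(predictors)
  num <- vapply(X, is.numeric, logical(1))
  X <- X[, num, drop = FALSE]
  # canonical column order: makes results invariant to how the caller
  # arranged the predictor columns
  X <- X[, sort(colnames(X)), drop = FALSE]
  if (any(!stats::complete.cases(X)) || any(is.na(response))) {
    sq_data_error("importance analysis requires complete cases")
  }
  if (nrow(X) < 10) sq_data_error("at least 10 observations required")
  if (length(response) != nrow(X)) sq_data_error("response length must match predictors")
  if (stats::sd(response) == 0) sq_data_error("constant response; importance undefined")
  X
}

#' Random-forest importance of soil indicators for a yield response
#'
#' Fits a regression random forest of the response on the indicator panel
#' and reports, per predictor, the out-of-bag permutation importance
#' (percent increase in mean-squared error when that predictor is permuted,
#' averaged over trees and scaled by its standard error — the conventional
#' %IncMSE), a rank, and a permutation p-value. The p-value comes from a
#' response-permutation null: the whole forest is refit
#' `config$n_permutations` times with the response shuffled, and
#' `p = (1 + #null >= observed) / (1 + n_permutations)`, so p-values are
#' never exactly zero. The forest's out-of-bag variance-explained is
#' reported alongside. Fully reproducible from the config seed.
#'
#' @param predictors Data frame of indicator columns.
#' @param response Numeric response (per-plot mean yield or SYI).
#' @param config An [importance_config()].
#' @param response_name Label carried into the result.
#' @return Object of class `forest_importance`: `table` data frame
#'   (`predictor`, `importance`, `p`, `rank`), `var_explained`, `config`.
#' @export
#' @examples
#' \donttest{
#' trial <- simulate_trial(trial_config(seed = 1))
#' ys <- yield_sustainability(trial$yields)
#' X <- trial$soil[, soil_indicators()$indicator]
#' imp <- forest_importance(X, ys$plot$mean_yield,
#'                          importance_config(n_trees = 200, seed = 1))
#' imp
#' }
forest_importance <- function(predictors, response, config = importance_config(),
                              response_name = "response") {
  stopifnot(inherits(config, "importance_config"))
  X <- check_importance_input(predictors, response)
  obs <- rf_importance_once(X, response, config$n_trees, config$seed)
  pv <- permutation_pvalues(X, response, config, .observed = obs$importance)
  imp <- obs$importance
  tab <- data.frame(predictor = names(imp), importance = unname(imp),
                    p = unname(pv[names(imp)]),
                    rank = rank(-imp, ties.method = "first"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, var_explained = obs$var_explained,
                 config = config, response_name = response_name),
            class = "forest_importance")
}

#' Response-permutation p-values for forest importance
#'
#' Builds each predictor's null importance distribution by refitting the
#' forest on permuted responses and applies the add-one estimator
#' `p = (1 + #null >= observed) / (1 + n_permutations)`.
#'
#' @inheritParams forest_importance
#' @param .observed Optional precomputed observed importances (internal use;
#'   avoids one redundant fit).
#' @return Named vector of per-predictor p-values in (0, 1].
#' @export
permutation_pvalues <- function(predictors, response, config = importance_config(),
                                .observed = NULL) {
  stopifnot(inherits(config, "importance_config"))
  X <- check_importance_input(predictors, response)
  if (is.null(.observed)) {
    .observed <- rf_importance_once(X, response, config$n_trees, config$seed)$importance
  }
  exceed <- stats::setNames(rep(0L, ncol(X)), colnames(X))
  for (b in seq_len(config$n_permutations)) {
    set.seed(config$seed + b)
    y_b <- sample(response)
    null_imp <- rf_importance_once(X, y_b, config$n_trees, config$seed + b)$importance
    exceed <- exceed + as.integer(null_imp[names(exceed)] >= .observed[names(exceed)])
  }
  (1 + exceed) / (1 + config$n_permutations)
}

#' @export
print.forest_importance <- function(x, digits = 3, ...) {
  cat(sprintf("Random-forest permutation importance for %s\n", x$response_name))
  cat(sprintf("  %d trees, %d response permutations, variance explained = %.1f%%\n",
              x$config$n_trees, x$config$n_permutations, x$var_explained))
  tab <- x$table
  tab$importance <- round(tab$importance, digits)
  tab$stars <- p_stars(tab$p)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.forest_importance <- function(x, ...) {
  tab <- x$table[order(x$table$importance), ]
  graphics::barplot(tab$importance, names.arg = tab$predictor, horiz = TRUE,
                    las = 1, xlab = "Increase in MSE (%)", ...)
  invisible(x)
}
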