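#' @keywords internal
#' Significance stars at the conventional two-sided thresholds.
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson correlations and two-sided p-values over the chosen
#' columns, with star labels (*** p < 0.001, ** p < 0.01, * p < 0.05). A
#' constant variable's correlations are undefined and reported as `NA` with
#' a flag. Optionally the p-values can be false-discovery-rate adjusted
#' across the matrix before starring (off by default, matching common
#' practice for descriptive correlation heatmaps).
#'
#' @param data Data frame.
#' @param variables Character vector of column names (default: all numeric
#'   columns).
#' @param adjust If `TRUE`, Benjamini-Hochberg adjust the off-diagonal
#'   p-values before computing stars.
#' @return Object of class `pearson_matrix`: list with `r`, `p`, `stars`,
#'   `n`, `constant` (names of constant variables), `adjust`.
#' @export
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + rnorm(10))
#' pearson_matrix(d)$r
pearson_matrix <- function(data, variables = NULL, adjust = FALSE) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  miss <- setdiff(variables, names(data))
  if (length(miss) > 0) sq_schema_error(sprintf("variable(s) not in data: %s",
                                                paste(miss, collapse = ", ")))
  X <- data[, variables, drop = FALSE]
  if (nrow(X) < 3) sq_data_error("at least 3 complete observations required")
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  constant <- variables[vapply(X, function(v) stats::sd(v) == 0, logical(1))]
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (variables[i] %in% constant || variables[j] %in% constant) next
      ct <- stats::cor.test(X[[i]], X[[j]], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (adjust) {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, stars = matrix(p_stars(p), k, k,
                                              dimnames = dimnames(p)),
                 n = nrow(X), constant = constant, adjust = adjust),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix (n = %d)%s\n", x$n,
              if (x$adjust) ", BH-adjusted stars" else ""))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "1"
  print(as.data.frame(disp))
  if (length(x$constant) > 0) {
    cat("Constant variable(s), correlations undefined:",
        paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simple linear regression of one index on another
#'
#' Ordinary least squares of `y` on `x` (e.g. the sustainable yield index on
#' the soil quality index), returning slope, intercept, R-squared, the
#' two-sided slope p-value and n. For simple regression R-squared equals
#' the squared Pearson correlation of x and y.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @return Object of class `sq_regression`: list with `slope`, `intercept`,
#'   `r_squared`, `p`, `n` and the underlying `lm` fit.
#' @export
#' @examples
#' fit_linear(1:10, 3 * (1:10) - 1)  # slope 3, intercept -1, R^2 = 1
fit_linear <- function(x, y) {
  if (length(x) != length(y)) sq_data_error("x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) sq_data_error("at least 3 points required")
  if (stats::sd(x) == 0) sq_data_error("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x), model = fit),
            class = "sq_regression")
}

#' @export
print.sq_regression <- function(x, digits = 5, ...) {
  cat(sprintf("y = %.*gx + %.*g, R^2 = %.*g, p = %.3g (n = %d)\n",
              digits, x$slope, digits, x$intercept, digits, x$r_squared,
              x$p, x$n))
  invisible(x)
}
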