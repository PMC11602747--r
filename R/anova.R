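#' One-way analysis of variance from explicit sums of squares
#'
#' Partitions the total sum of squares into between- and within-group
#' components, forms `F = MSB / MSW`, and takes the p-value from the F
#' distribution with (k-1, N-k) degrees of freedom. The decomposition
#' `SST = SSB + SSW` is part of the contract and is exposed for audit. A
#' degenerate case with zero within-group variance but nonzero between is
#' reported as infinite F with p = 0 and a flag rather than an error.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param response Optional response name carried into the result.
#' @return Object of class `sq_anova`: list with `response`, `df_between`,
#'   `df_within`, `F`, `p`, `ss_between`, `ss_within`, `ss_total`,
#'   `zero_within_variance`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))  # F = 1.5
one_way_anova <- function(values, groups, response = "response") {
  g <- factor(groups)
  if (any(is.na(values)) || any(is.na(g))) sq_data_error("missing values in ANOVA input")
  if (nlevels(g) < 2) sq_data_error("ANOVA needs at least 2 groups")
  n_per <- table(g)
  if (any(n_per < 2)) {
    sq_data_error(sprintf("group(s) with fewer than 2 observations: %s",
                          paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  grand <- mean(values)
  gm <- tapply(values, g, mean)
  ssb <- sum(as.numeric(n_per) * (gm - grand)^2)
  ssw <- sum((values - gm[g])^2)
  sst <- sum((values - grand)^2)
  dfb <- nlevels(g) - 1L
  dfw <- length(values) - nlevels(g)
  msw <- ssw / dfw
  zero_within <- msw == 0 && ssb > 0
  if (zero_within) {
    Fv <- Inf; p <- 0
  } else if (msw == 0) {
    Fv <- 0; p <- 1  # all values identical
  } else {
    Fv <- (ssb / dfb) / msw
    p <- stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(response = response, df_between = dfb, df_within = dfw,
                 F = Fv, p = p, ss_between = ssb, ss_within = ssw,
                 ss_total = sst, zero_within_variance = zero_within),
            class = "sq_anova")
}

#' @export
print.sq_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA for %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$response, x$df_between, x$df_within, x$F, x$p))
  if (x$zero_within_variance) cat("  (zero within-group variance; F reported as infinite)\n")
  invisible(x)
}

#' Normality and variance-homogeneity checks for grouped data
#'
#' Shapiro-Wilk per group and Levene's test across groups, each with a pass
#' flag at the chosen alpha. Groups too small (< 3) or constant are flagged
#' not-assessable for normality rather than failing.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the pass flags (default 0.05).
#' @param center Centering for Levene's statistic: `"mean"` (classic Levene,
#'   default) or `"median"` (Brown-Forsythe).
#' @return Object of class `assumption_report` with `shapiro` (per-group
#'   data frame with `W`, `p`, `pass`, `assessable`) and `levene`
#'   (statistic, df, p, pass).
#' @export
check_assumptions <- function(values, groups, alpha = 0.05,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  sh <- lapply(levels(g), function(lev) {
    v <- values[g == lev]
    if (length(v) < 3 || stats::sd(v) == 0) {
      data.frame(group = lev, W = NA_real_, p = NA_real_, pass = NA,
                 assessable = FALSE, stringsAsFactors = FALSE)
    } else {
      t <- stats::shapiro.test(v)
      data.frame(group = lev, W = unname(t$statistic), p = t$p.value,
                 pass = t$p.value >= alpha, assessable = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  lev <- car::leveneTest(values ~ g, center = if (center == "mean") mean else stats::median)
  levene <- list(statistic = lev[1, "F value"], df = c(lev[1, "Df"], lev[2, "Df"]),
                 p = lev[1, "Pr(>F)"], pass = lev[1, "Pr(>F)"] >= alpha)
  structure(list(shapiro = do.call(rbind, sh), levene = levene,
                 alpha = alpha, center = center),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Assumption checks (alpha = %g)\n", x$alpha))
  cat("Shapiro-Wilk per group:\n")
  print(x$shapiro, row.names = FALSE)
  cat(sprintf("Levene (%s-centered): F(%d, %d) = %.3f, p = %.4g [%s]\n",
              x$center, x$levene$df[1], x$levene$df[2], x$levene$statistic,
              x$levene$p, if (isTRUE(x$levene$pass)) "pass" else "fail"))
  invisible(x)
}
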