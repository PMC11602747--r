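#' Pairwise comparison p-values between treatments
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param method `"tukey"` (studentized-range family from
#'   [stats::TukeyHSD()], default) or `"lsd"` (unadjusted pairwise t tests
#'   with a pooled variance).
#' @return Symmetric matrix of pairwise p-values (diagonal `NA`).
#' @export
pairwise_p <- function(values, groups, method = c("tukey", "lsd")) {
  method <- match.arg(method)
  g <- factor(groups)
  levs <- levels(g)
  P <- matrix(NA_real_, length(levs), length(levs), dimnames = list(levs, levs))
  if (method == "tukey") {
    fit <- stats::aov(values ~ g)
    tk <- stats::TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      P[a, b] <- P[b, a] <- tk[i, "p adj"]
    }
  } else {
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "none")$p.value
    for (a in rownames(pt)) for (b in colnames(pt)) {
      if (!is.na(pt[a, b])) P[a, b] <- P[b, a] <- pt[a, b]
    }
  }
  P
}

#' @keywords internal
#' Insert-and-absorb compact letter display.
#'
#' Starts from one column containing all groups; for every significant pair
#' the columns containing both members are split into two (one without each
#' member); columns that become subsets of others are absorbed. The result:
#' two groups share a letter exactly when their difference is
#' nonsignificant, with a minimal letter set. Letters are ordered so the
#' group with the largest mean gets "a" first.
insert_absorb <- function(sig_pairs, levs, means) {
  cols <- list(levs)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- unique(new_cols[keep])
  }
  # order columns by the best (largest-mean) group they contain
  best <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-best)]
  out <- stats::setNames(rep("", length(levs)), levs)
  for (i in seq_along(cols)) {
    for (gname in cols[[i]]) out[gname] <- paste0(out[gname], letters[i])
  }
  out
}

#' Compact letter display for treatment comparisons
#'
#' Runs all pairwise comparisons by the chosen family and assigns lowercase
#' letters by the insert-and-absorb convention: two treatments share a
#' letter if and only if their pairwise difference is nonsignificant at
#' `alpha`. The treatment with the largest mean receives "a".
#'
#' @inheritParams pairwise_p
#' @param alpha Significance level (default 0.05).
#' @return Object of class `group_letters`: list with `letters` (named
#'   character vector), `p` (pairwise matrix), `means`, `method`, `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(6, 0), rnorm(6, 10), rnorm(6, 20))
#' g <- rep(c("CK", "CF", "M1"), each = 6)
#' pairwise_letters(v, g)$letters
pairwise_letters <- function(values, groups, method = c("tukey", "lsd"), alpha = 0.05) {
  method <- match.arg(method)
  g <- factor(groups)
  P <- pairwise_p(values, g, method)
  means <- tapply(values, g, mean)
  levs <- levels(g)
  sig <- which(P < alpha & upper.tri(P), arr.ind = TRUE)
  sig_pairs <- data.frame(a = levs[sig[, 1]], b = levs[sig[, 2]],
                          stringsAsFactors = FALSE)
  letts <- insert_absorb(sig_pairs, levs, means)
  structure(list(letters = letts, p = P, means = means,
                 method = method, alpha = alpha),
            class = "group_letters")
}

#' @export
print.group_letters <- function(x, digits = 3, ...) {
  ord <- order(-x$means)
  df <- data.frame(group = names(x$means)[ord],
                   mean = round(as.numeric(x$means)[ord], digits),
                   letters = unname(x$letters[ord]),
                   stringsAsFactors = FALSE)
  cat(sprintf("Compact letter display (%s, alpha = %g):\n", x$method, x$alpha))
  print(df, row.names = FALSE)
  invisible(x)
}
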