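#' Principal-component communalities of the soil indicators
#'
#' Standardizes each indicator to zero mean and unit variance, takes the
#' eigendecomposition of the indicator correlation matrix, retains
#' components by the chosen rule, and returns each indicator's communality:
#' the share of its (unit) variance reproduced by the retained components,
#' i.e. the sum of its squared loadings. Communalities lie in [0, 1] and are
#' the numerators of the index weights (see
#' [weights_from_communalities()]).
#'
#' @param x Data frame containing indicator columns, or a numeric matrix
#'   (plots x indicators).
#' @param retention Retention rule: `"kaiser"` (eigenvalue >= 1, default),
#'   `"all"` (every component; all communalities become 1), `"fixed"`
#'   (first `n_components`), or `"cumulative"` (smallest set reaching
#'   `cum_var` of total variance).
#' @param n_components Number of components for `retention = "fixed"`.
#' @param cum_var Proportion of variance for `retention = "cumulative"`.
#' @return List of class `communality` with `communalities`, `eigenvalues`,
#'   `retained` (indices), `loadings` and `retention`.
#' @export
#' @examples
#' soil <- simulate_trial(trial_config(seed = 1))$soil
#' pca_communalities(soil)$communalities
pca_communalities <- function(x, retention = c("kaiser", "all", "fixed", "cumulative"),
                              n_components = NULL, cum_var = NULL) {
  retention <- match.arg(retention)
  if (is.data.frame(x)) {
    inds <- intersect(indicator_names(), names(x))
    if (length(inds) == 0) inds <- names(x)[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x[, inds, drop = FALSE])
  }
  if (!is.numeric(x)) sq_data_error("indicator table must be numeric")
  if (nrow(x) < 3) sq_data_error("at least 3 plots are required for communality extraction")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    sq_data_error(sprintf("constant indicator(s): %s",
                          paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  C <- stats::cor(x)
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  # guard against numerically negative eigenvalues of a rank-deficient panel
  drop <- lam < 1e-10
  if (any(drop)) {
    message(sprintf("dropping %d near-zero eigenvalue(s) below 1e-10", sum(drop)))
    lam[drop] <- 0
  }
  retained <- switch(retention,
    kaiser     = which(lam >= 1),
    all        = which(lam > 0),
    fixed      = {
      if (is.null(n_components)) sq_config_error("retention = 'fixed' needs n_components")
      seq_len(min(n_components, sum(lam > 0)))
    },
    cumulative = {
      if (is.null(cum_var)) sq_config_error("retention = 'cumulative' needs cum_var")
      seq_len(which(cumsum(lam) / sum(lam) >= cum_var)[1])
    }
  )
  if (length(retained) == 0) retained <- 1L  # always keep the leading component
  load <- sweep(e$vectors, 2, sqrt(pmax(lam, 0)), `*`)
  rownames(load) <- colnames(C)
  comm <- rowSums(load[, retained, drop = FALSE]^2)
  comm <- pmin(pmax(comm, 0), 1)
  structure(
    list(communalities = comm, eigenvalues = lam, retained = retained,
         loadings = load, retention = retention),
    class = "communality"
  )
}

#' Index weights from communalities
#'
#' Each indicator's weight is its communality divided by the sum of all
#' communalities, so the weights are nonnegative and sum to one.
#'
#' @param communalities Numeric vector of communalities (or a
#'   `communality` object).
#' @return Object of class `weight_vector`: list with `weights`,
#'   `communalities`, and (when available) `eigenvalues` and `retention`.
#' @export
#' @examples
#' weights_from_communalities(c(a = 0.9, b = 0.3))$weights  # 0.75, 0.25
weights_from_communalities <- function(communalities) {
  extra <- list()
  if (inherits(communalities, "communality")) {
    extra <- communalities[c("eigenvalues", "retention")]
    communalities <- communalities$communalities
  }
  if (any(communalities < 0)) sq_data_error("communalities must be >= 0")
  s <- sum(communalities)
  if (s <= 0) sq_data_error("all communalities are zero; weights undefined")
  structure(
    c(list(weights = communalities / s, communalities = communalities), extra),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Communality-ratio indicator weights (sum = 1):\n")
  print(round(rbind(communality = x$communalities, weight = x$weights), digits))
  invisible(x)
}
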