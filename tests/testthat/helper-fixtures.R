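# Small in-code fixtures shared across the suite.

# A minimal long-format yield table (n treatments x n blocks x years).
make_yield_fixture <- function(treatments = c("CK", "CF", "M1"),
                               blocks = 1, years = 2014:2015,
                               yield = 1000) {
  g <- expand.grid(block = blocks, treatment = treatments, year = years,
                   stringsAsFactors = FALSE)
  g$plot_id <- sprintf("%s_b%d", g$treatment, g$block)
  g$yield <- yield + seq_len(nrow(g))
  g[, c("plot_id", "block", "treatment", "year", "yield")]
}

# A small soil table with all 12 indicators, values jittered around the
# control anchors.
make_soil_fixture <- function(n_per_treatment = 2,
                              treatments = c("CK", "CF", "M1")) {
  base <- anchor_set()$ck
  rows <- list()
  k <- 0
  for (tr in treatments) {
    for (b in seq_len(n_per_treatment)) {
      k <- k + 1
      vals <- base * (1 + 0.05 * ((k %% 5) - 2))
      rows[[k]] <- cbind(
        data.frame(plot_id = sprintf("%s_b%d", tr, b), treatment = tr,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(vals))
      )
    }
  }
  do.call(rbind, rows)
}

write_csv_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.csv")
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# Brute-force chain oracle: explicit-loop scoring, communalities and SQI.
# Independent of the package implementation (works from first principles).
oracle_chain <- function(values, directions, retain_rule = "kaiser") {
  n <- nrow(values); k <- ncol(values)
  scores <- matrix(NA_real_, n, k, dimnames = dimnames(values))
  for (j in seq_len(k)) {
    lo <- min(values[, j]); hi <- max(values[, j])
    for (i in seq_len(n)) {
      scores[i, j] <- if (directions[j] == "more_is_better") {
        (values[i, j] - lo) / (hi - lo)
      } else {
        (hi - values[i, j]) / (hi - lo)
      }
    }
  }
  z <- scale(values)
  C <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    C[a, b] <- sum(z[, a] * z[, b]) / (n - 1)
  }
  s <- svd(z / sqrt(n - 1))          # singular values^2 = eigenvalues of C
  lam <- s$d^2
  retained <- if (retain_rule == "kaiser") which(lam >= 1) else seq_along(lam)
  if (length(retained) == 0) retained <- 1L
  comm <- numeric(k)
  for (j in seq_len(k)) {
    for (m in retained) comm[j] <- comm[j] + lam[m] * s$v[j, m]^2
  }
  w <- comm / sum(comm)
  sqi <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(k)) sqi[i] <- sqi[i] + w[j] * scores[i, j]
  list(scores = scores, eigenvalues = lam, communalities = comm,
       weights = w, sqi = sqi)
}

# Direct-arithmetic SYI oracle.
oracle_syi <- function(y, sample_sd = TRUE) {
  m <- sum(y) / length(y)
  dev <- sum((y - m)^2)
  s <- sqrt(dev / (length(y) - if (sample_sd) 1 else 0))
  (m - s) / max(y)
}
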