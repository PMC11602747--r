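test_that("one-way ANOVA reproduces the hand-computed toy case", {
  a <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  # identical groups: no between-group variance
  a0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(a0$F, 0)
})

test_that("ANOVA agrees with the base-R route and satisfies SST = SSB + SSW", {
  for (seed in 1:25) {
    set.seed(seed)
    g <- rep(letters[1:4], each = 5)
    v <- stats::rnorm(20, mean = rep(c(0, 1, 0.5, 2), each = 5))
    a <- one_way_anova(v, g)
    ref <- stats::oneway.test(v ~ factor(g), var.equal = TRUE)
    expect_equal(a$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p, ref$p.value, tolerance = 1e-10)
    expect_lt(abs(a$ss_total - (a$ss_between + a$ss_within)), 1e-8)
    # location invariance
    a_shift <- one_way_anova(v + 1234.5, g)
    expect_equal(a_shift$F, a$F, tolerance = 1e-9)
    expect_equal(a_shift$p, a$p, tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA inputs are handled per contract", {
  expect_error(one_way_anova(1:5, rep("a", 5)), class = "soilqi_data_error")
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")),
               class = "soilqi_data_error")
  z <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.infinite(z$F))
  expect_equal(z$p, 0)
  expect_true(z$zero_within_variance)
})

test_that("assumption checks calibrate under the null and flag strong alternatives", {
  # equal-variance Gaussian groups: each check passes at its nominal rate
  lev_pass <- sh_pass <- sh_total <- 0
  for (s in 1:100) {
    set.seed(s)
    v <- stats::rnorm(90)
    g <- rep(c("a", "b", "c"), each = 30)
    rep_ <- check_assumptions(v, g)
    lev_pass <- lev_pass + rep_$levene$pass
    sh_pass <- sh_pass + sum(rep_$shapiro$pass)
    sh_total <- sh_total + nrow(rep_$shapiro)
  }
  expect_gte(lev_pass, 90)
  expect_gte(sh_pass / sh_total, 0.90)

  # one group's variance 25x the others: homogeneity rejected
  lev_fail <- 0
  for (s in 1:50) {
    set.seed(s)
    v <- c(stats::rnorm(30, sd = 1), stats::rnorm(30, sd = 1), stats::rnorm(30, sd = 5))
    rep_ <- check_assumptions(v, rep(c("a", "b", "c"), each = 30))
    lev_fail <- lev_fail + !rep_$levene$pass
  }
  expect_gte(lev_fail, 45)

  # constant group: normality not assessable
  rep0 <- check_assumptions(c(5, 5, 5, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_false(rep0$shapiro$assessable[rep0$shapiro$group == "a"])
})

test_that("compact letters separate when separation is overwhelming", {
  set.seed(2)
  v <- c(stats::rnorm(6, 0, 0.01), stats::rnorm(6, 10, 0.01), stats::rnorm(6, 20, 0.01))
  g <- rep(c("low", "mid", "high"), each = 6)
  l <- pairwise_letters(v, g)
  expect_equal(sort(unname(l$letters)), c("a", "b", "c"))
  # largest mean gets "a"
  expect_equal(unname(l$letters["high"]), "a")
  expect_equal(unname(l$letters["low"]), "c")
})

test_that("identically drawn groups usually share one letter", {
  share <- 0
  for (s in 1:50) {
    set.seed(s)
    v <- stats::rnorm(30)
    g <- rep(letters[1:5], each = 6)
    l <- pairwise_letters(v, g)
    share <- share + all(l$letters == "a")
  }
  expect_gte(share, 45)
})

test_that("two clearly different groups get distinct letters", {
  v <- c(1, 2, 3, 2, 3, 4) * 100
  v <- c(stats::rnorm(6, 0, 0.1), stats::rnorm(6, 50, 0.1))
  l <- pairwise_letters(v, rep(c("a", "b"), each = 6))
  expect_equal(sort(unname(l$letters)), c("a", "b"))
})

test_that("letter sharing encodes exactly the nonsignificant pairs", {
  # constructed overlap pattern: a < b < c with b not distinguishable from
  # either neighbor but a and c distinct
  set.seed(4)
  v <- c(stats::rnorm(6, 0, 1), stats::rnorm(6, 2.2, 1), stats::rnorm(6, 4.4, 1))
  g <- rep(c("a", "b", "c"), each = 6)
  l <- pairwise_letters(v, g)
  shares <- function(x, y) {
    any(strsplit(l$letters[[x]], "")[[1]] %in% strsplit(l$letters[[y]], "")[[1]])
  }
  P <- l$p
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(shares(pair[1], pair[2]), P[pair[1], pair[2]] >= l$alpha)
  }
})

test_that("letters agree with multcomp's display on a fixture", {
  skip_if_not_installed("multcomp")
  set.seed(6)
  d <- data.frame(v = c(stats::rnorm(6, 0), stats::rnorm(6, 1.5), stats::rnorm(6, 4),
                        stats::rnorm(6, 4.2)),
                  g = factor(rep(c("t1", "t2", "t3", "t4"), each = 6)))
  ours <- pairwise_letters(d$v, d$g)
  glht <- multcomp::glht(stats::aov(v ~ g, d), linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht)$mcletters$Letters
  # same sharing structure (letter labels may differ by ordering convention)
  share_ours <- outer(names(ours$letters), names(ours$letters),
                      Vectorize(function(x, y) {
                        any(strsplit(ours$letters[[x]], "")[[1]] %in%
                            strsplit(ours$letters[[y]], "")[[1]])
                      }))
  share_ref <- outer(names(ref), names(ref),
                     Vectorize(function(x, y) {
                       any(strsplit(ref[[x]], "")[[1]] %in% strsplit(ref[[y]], "")[[1]])
                     }))
  expect_equal(share_ours[order(names(ours$letters)), order(names(ours$letters))],
               share_ref[order(names(ref)), order(names(ref))])
})

test_that("Pearson matrix matches the covariance-quotient oracle and stars map", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.5, 2.9, 1.4, 4.9, 4.1)
  d <- data.frame(x = x, y = y)
  pm <- pearson_matrix(d)
  n <- 5
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pm$r["x", "y"], num / den, tolerance = 1e-12)
  expect_true(pm$r["x", "y"] <= 1 && pm$r["x", "y"] >= -1)
  expect_equal(pm$r, t(pm$r))
  expect_equal(diag(pm$r), c(x = 1, y = 1))

  # perfect linearity and sign reflection
  d2 <- data.frame(a = 1:6, b = 2 * (1:6) + 1, c = -(1:6))
  pm2 <- pearson_matrix(d2)
  expect_equal(pm2$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(pm2$r["a", "c"], -1, tolerance = 1e-12)

  # stars follow the 0.05 / 0.01 / 0.001 thresholds
  p <- pm2$p
  s <- pm2$stars
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (is.na(p[i, j])) next
    expected <- if (p[i, j] < 0.001) "***" else if (p[i, j] < 0.01) "**"
                else if (p[i, j] < 0.05) "*" else ""
    expect_equal(s[i, j], expected)
  }

  # constant variable flagged, correlations undefined
  d3 <- data.frame(a = 1:5, k = rep(2, 5))
  pm3 <- pearson_matrix(d3)
  expect_equal(pm3$constant, "k")
  expect_true(is.na(pm3$r["a", "k"]))
})

test_that("linear fits recover exact lines and match closed-form least squares", {
  f <- suppressWarnings(fit_linear(1:10, 3 * (1:10) - 1))  # exact fit warns in summary.lm
  expect_equal(f$slope, 3, tolerance = 1e-12)
  expect_equal(f$intercept, -1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  x <- c(0.4, 1.9, 3.2, 4.4)
  y <- c(1.1, 2.3, 2.1, 4.8)
  f4 <- fit_linear(x, y)
  # closed-form normal equations
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
           (sum(x^2) - length(x) * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(f4$slope, slope, tolerance = 1e-10)
  expect_equal(f4$intercept, intercept, tolerance = 1e-10)
  # R^2 equals the squared Pearson correlation in simple regression
  expect_equal(f4$r_squared, cor(x, y)^2, tolerance = 1e-12)

  expect_error(fit_linear(rep(2, 5), 1:5), class = "soilqi_data_error")
})

test_that("independent response yields near-zero R-squared at large n", {
  low <- 0
  for (s in 1:20) {
    set.seed(s)
    f <- fit_linear(stats::rnorm(200), stats::rnorm(200))
    low <- low + (f$r_squared < 0.05)
  }
  expect_gte(low, 18)
})
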