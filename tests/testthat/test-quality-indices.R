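make_values <- function(n = 5, k = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * k, 1, 10), n, k,
              dimnames = list(NULL, paste0("v", seq_len(k))))
  m
}

values_as_soil <- function(m) {
  df <- data.frame(plot_id = sprintf("p%d", seq_len(nrow(m))),
                   treatment = rep_len(c("CK", "CF", "M1"), nrow(m)),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(m))
}

custom_meta <- function(k, directions) {
  data.frame(indicator = paste0("v", seq_len(k)),
             unit = "u", direction = directions, stringsAsFactors = FALSE)
}

test_that("min-max scoring honors bounds, direction, and midpoints", {
  m <- cbind(v1 = c(1.2, 1.3, 1.4))
  soil <- values_as_soil(m)
  sc_less <- score_indicators(soil, custom_meta(1, "less_is_better"))
  expect_equal(as.numeric(sc_less$scores), c(1, 0.5, 0))
  sc_more <- score_indicators(soil, custom_meta(1, "more_is_better"))
  expect_equal(as.numeric(sc_more$scores), c(0, 0.5, 1))
  # bound cases: min scores 0, max scores 1 (more-is-better)
  expect_equal(sc_more$scores[1, 1], 0)
  expect_equal(sc_more$scores[3, 1], 1)
  expect_equal(sc_more$bounds$xmin, 1.2)
  expect_equal(sc_more$bounds$xmax, 1.4)
})

test_that("degenerate indicators error by default and can be dropped", {
  m <- cbind(v1 = c(2, 2, 2), v2 = c(1, 2, 3))
  soil <- values_as_soil(m)
  meta <- custom_meta(2, c("more_is_better", "more_is_better"))
  expect_error(score_indicators(soil, meta), "v1", class = "soilqi_data_error")
  expect_warning(sc <- score_indicators(soil, meta, on_degenerate = "drop"), "v1")
  expect_equal(colnames(sc$scores), "v2")
})

test_that("scoring is invariant to positive affine transforms of a column", {
  for (seed in 1:20) {
    m <- make_values(6, 4, seed)
    soil <- values_as_soil(m)
    meta <- custom_meta(4, c("more_is_better", "less_is_better",
                             "more_is_better", "more_is_better"))
    s0 <- score_indicators(soil, meta)$scores
    m2 <- m
    m2[, 2] <- 3.7 * m2[, 2] + 11
    s1 <- score_indicators(values_as_soil(m2), meta)$scores
    expect_equal(s1, s0, tolerance = 1e-12)
  }
})

test_that("communalities match an independent decomposition and its limits", {
  # rank-1 structure: two perfectly correlated indicators
  x <- cbind(v1 = c(1, 2, 3, 4), v2 = c(2, 4, 6, 8) + 1)
  cm <- pca_communalities(x, retention = "kaiser")
  expect_equal(unname(cm$communalities), c(1, 1), tolerance = 1e-12)
  expect_equal(length(cm$retained), 1)

  # retaining every component recovers all variance
  m <- make_values(6, 4, seed = 3)
  cm_all <- pca_communalities(m, retention = "all")
  expect_equal(unname(cm_all$communalities), rep(1, 4), tolerance = 1e-10)

  # 5 x 3 fixture vs the svd-based oracle
  m53 <- make_values(5, 3, seed = 7)
  or <- oracle_chain(m53, rep("more_is_better", 3))
  cm53 <- pca_communalities(m53)
  expect_equal(unname(cm53$communalities), or$communalities, tolerance = 1e-8)
  expect_equal(cm53$eigenvalues, or$eigenvalues, tolerance = 1e-8)

  expect_error(pca_communalities(m53[1:2, ]), class = "soilqi_data_error")
  expect_error(pca_communalities(cbind(v1 = c(1, 1, 1), v2 = c(1, 2, 3))),
               class = "soilqi_data_error")
})

test_that("communality-ratio weights normalize and scale-cancel", {
  w <- weights_from_communalities(c(a = 0.9, b = 0.3))
  expect_equal(unname(w$weights), c(0.75, 0.25))
  w12 <- weights_from_communalities(rep(0.4, 12))
  expect_equal(unname(w12$weights), rep(1 / 12, 12))
  for (seed in 1:50) {
    set.seed(seed)
    ci <- stats::runif(8)
    expect_lt(abs(sum(weights_from_communalities(ci)$weights) - 1), 1e-12)
    # positive rescaling of all communalities leaves weights unchanged
    expect_equal(weights_from_communalities(5.3 * ci)$weights,
                 weights_from_communalities(ci)$weights, tolerance = 1e-12)
  }
  expect_error(weights_from_communalities(c(0, 0)), class = "soilqi_data_error")
})

test_that("SQI is the exact weighted sum and aggregates by treatment", {
  m <- make_values(4, 3, seed = 5)
  soil <- values_as_soil(m)
  meta <- custom_meta(3, rep("more_is_better", 3))
  sc <- score_indicators(soil, meta)
  w <- weights_from_communalities(stats::setNames(c(0.8, 0.5, 0.2), colnames(m)))
  res <- compute_sqi(sc, w)
  manual <- sapply(seq_len(4), function(i) sum(w$weights * sc$scores[i, ]))
  expect_equal(res$plot$sqi, manual, tolerance = 1e-12)

  # uniform weights reduce SQI to the row mean of scores
  wu <- stats::setNames(rep(1 / 3, 3), colnames(m))
  expect_equal(compute_sqi(sc, wu)$plot$sqi, unname(rowMeans(sc$scores)),
               tolerance = 1e-12)

  # all scores 1 gives SQI exactly 1
  sc1 <- sc
  sc1$scores[] <- 1
  expect_equal(compute_sqi(sc1, w)$plot$sqi, rep(1, 4))

  # mismatched indicator sets are reported with the symmetric difference
  w_bad <- stats::setNames(c(0.5, 0.5), c("v1", "zz"))
  expect_error(compute_sqi(sc, w_bad), "zz", class = "soilqi_data_error")
})

test_that("the full index chain matches the explicit-loop oracle", {
  for (seed in c(2, 13, 31)) {
    k <- 3 + seed %% 4
    m <- make_values(6, k, seed)
    dirs <- rep(c("more_is_better", "less_is_better"), length.out = k)
    soil <- values_as_soil(m)
    fit <- soil_quality(soil, meta = custom_meta(k, dirs))
    or <- oracle_chain(m, dirs)
    expect_equal(unname(fit$scores$scores), unname(or$scores), tolerance = 1e-10)
    expect_equal(unname(coef(fit)), or$weights, tolerance = 1e-10)
    expect_equal(fit$sqi$sqi, or$sqi, tolerance = 1e-10)
  }
})

test_that("SQI is bounded and monotone in indicator improvements", {
  trial <- simulate_trial(trial_config(seed = 21))
  fit <- soil_quality(trial$soil)
  expect_true(all(fit$sqi$sqi >= 0 & fit$sqi$sqi <= 1))
  # each data-derived bound is attained by some plot
  expect_true(all(apply(fit$scores$scores, 2, min) == 0))
  expect_true(all(apply(fit$scores$scores, 2, max) == 1))

  # with fixed bounds and fixed weights, raising a more-is-better indicator
  # never lowers any plot's SQI
  soil2 <- trial$soil
  soil2$som <- soil2$som + 1.5
  p2 <- predict(fit, soil2)
  expect_true(all(p2 - fit$sqi$sqi >= -1e-12))
  # and lowering a less-is-better indicator never lowers it
  soil3 <- trial$soil
  soil3$bd <- pmax(soil3$bd - 0.05, 0.5)
  p3 <- predict(fit, soil3)
  expect_true(all(p3 - fit$sqi$sqi >= -1e-12))
})

test_that("soil_quality methods expose weights, fits and predictions", {
  trial <- simulate_trial(trial_config(seed = 8))
  fit <- soil_quality(trial$soil)
  expect_s3_class(fit, "soil_quality")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_length(fitted(fit), 30)
  expect_equal(unname(predict(fit, trial$soil)), fit$sqi$sqi, tolerance = 1e-12)
  sm <- summary(fit)
  expect_equal(nrow(sm$weights), 12)
  expect_output(print(fit), "Soil quality index")
})
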