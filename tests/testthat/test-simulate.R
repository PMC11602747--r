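test_that("default config reproduces the published anchor means", {
  m <- trial_config()$indicator_means
  a <- anchor_set()
  expect_equal(m["CK", "bd"], 1.35)
  expect_equal(m["CK", "ph"], 7.04)
  expect_equal(m["CK", "no3_n"], 8.18)
  expect_equal(m["CF", "no3_n"], 25.32)
  expect_equal(m["M3", "bd"], 1.22)
  expect_equal(m["M3", "ph"], 7.30)
  expect_equal(m["M1", "som"], 12.80 * 1.9956)
  expect_equal(m["M1", "tn"], 0.61 * 1.9033)
  expect_equal(m["M1", "nh4_n"], 3.10 * 2.5635)
  expect_equal(m["CF", "bd"], 1.35 * 1.0974)
  expect_equal(m["M1", "ur"] / m["CK", "ur"], 2.0000)
  expect_equal(m["M2", "ur"] / m["CK", "ur"], 1.7117)
  expect_equal(m["M3", "cat"] / m["CK", "cat"], 1.4563)
  # baseline panel
  expect_equal(unname(a$ck[c("som", "tn", "alkali_n", "ap", "ak")]),
               c(12.80, 0.61, 49.00, 28.30, 191.00))
})

test_that("zero-noise generation reproduces configured means exactly", {
  ym <- default_yield_model <- trial_config()$yield_model
  ym$resid_sd <- 0
  cfg <- trial_config(seed = 9, yield_model = ym, block_sd = 0, indicator_cv = 0)
  y <- simulate_yields(cfg)
  for (tr in c("CK", "M1")) {
    sub <- y[y$treatment == tr & y$block == 3, ]
    m <- ym[ym$treatment == tr, ]
    expect_equal(sub$yield, m$base + m$trend * (sub$year - min(sub$year)))
  }
  soil <- simulate_soil(cfg)
  for (tr in treatment_levels()) {
    sub <- soil[soil$treatment == tr, indicator_names()]
    expect_equal(as.numeric(as.matrix(sub)),
                 rep(cfg$indicator_means[tr, ], each = cfg$n_blocks),
                 ignore_attr = TRUE)
  }
})

test_that("generation is deterministic in the seed", {
  a <- simulate_trial(trial_config(seed = 77))
  b <- simulate_trial(trial_config(seed = 77))
  expect_identical(a, b)
  c <- simulate_trial(trial_config(seed = 78))
  expect_false(identical(a$yields$yield, c$yields$yield))
})

test_that("default generator passes the (5 treatments, 6 blocks, 10 years) design", {
  trial <- simulate_trial(trial_config(seed = 4))
  expect_equal(nrow(trial$yields), 300)
  expect_equal(nrow(trial$soil), 30)
  expect_equal(nrow(validate_design(trial$yields, trial$soil)), 0)
})

test_that("long-run yield means sit within 3 generator SDs of configured means", {
  cfg <- trial_config(seed = 1)
  ym <- cfg$yield_model
  seeds <- seq(101, 120)
  grand <- sapply(seeds, function(s) {
    y <- simulate_yields(trial_config(seed = s))
    tapply(y$yield, y$treatment, mean)[treatment_levels()]
  })
  for (tr in treatment_levels()) {
    m <- ym[ym$treatment == tr, ]
    expected <- m$base + m$trend * mean(cfg$years - cfg$years[1])
    # per-seed grand mean sd: block effects averaged over 6 blocks,
    # residuals over 60 plot-years
    sd_one <- sqrt(cfg$block_sd^2 / cfg$n_blocks +
                   m$resid_sd^2 / (cfg$n_blocks * length(cfg$years)))
    expect_lt(abs(mean(grand[tr, ]) - expected),
              3 * sd_one / sqrt(length(seeds)))
  }
})

test_that("indicator correlation model is realized in large samples", {
  cfg <- trial_config(seed = 5, rho = 0.7)
  soil <- simulate_soil(cfg, n_per_treatment = 2000)
  sub <- soil[soil$treatment == "CK", ]
  expect_lt(abs(cor(sub$som, sub$tn) - 0.7), 0.05)
  # BD is negatively coupled to the nutrient block at -rho/2
  expect_lt(abs(cor(sub$bd, sub$som) - (-0.35)), 0.06)
})

test_that("default CK nitrate mean matches its anchor within sampling error", {
  cfg <- trial_config(seed = 6)
  soil <- simulate_soil(cfg)
  ck <- soil$no3_n[soil$treatment == "CK"]
  sd_model <- 8.18 * cfg$indicator_cv["no3_n"]
  expect_lt(abs(mean(ck) - 8.18), 3 * sd_model / sqrt(length(ck)) + 1e-9)
})

test_that("invalid generator configs are rejected", {
  expect_error(trial_config(rho = 1), class = "soilqi_config_error")
  expect_error(trial_config(rho = -0.1), class = "soilqi_config_error")
  m <- trial_config()$indicator_means
  m["CK", "bd"] <- -1
  expect_error(trial_config(indicator_means = m), class = "soilqi_config_error")
  ym <- trial_config()$yield_model
  ym$resid_sd[1] <- -5
  expect_error(trial_config(yield_model = ym), class = "soilqi_config_error")
})

test_that("the yield shock hits only its configured treatment-year", {
  cfg_off <- trial_config(seed = 11)
  cfg_on <- trial_config(seed = 11, shock = list(treatment = "M1", year = 2019,
                                                 multiplier = 0.75, enabled = TRUE))
  y0 <- simulate_yields(cfg_off)
  y1 <- simulate_yields(cfg_on)
  hit <- y0$treatment == "M1" & y0$year == 2019
  expect_equal(y1$yield[hit], 0.75 * y0$yield[hit])
  expect_identical(y1$yield[!hit], y0$yield[!hit])
})
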