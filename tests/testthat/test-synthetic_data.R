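test_that("the Loewe root reduces at the boundary and matches the grid oracle", {
  fit_a <- median_effect_model(10, 1)
  fit_b <- median_effect_model(100, 2)
  expect_equal(loewe_effect(fit_a, fit_b, 7, 0), effect_at_dose(fit_a, 7))
  expect_equal(loewe_effect(fit_a, fit_b, 0, 60), effect_at_dose(fit_b, 60))
  # sham at the median dose
  expect_equal(loewe_effect(fit_a, fit_a, 4, 6), 0.5, tolerance = 1e-9)
  # asymmetric case against a dense grid scan of the additivity residual
  fa <- loewe_effect(fit_a, fit_b, 5, 50)
  fa_oracle <- oracle_loewe_grid(10, 1, 100, 2, 5, 50)
  expect_equal(fa, fa_oracle, tolerance = 1e-5)
  # the additivity residual is strictly monotone in fa for positive slopes
  set.seed(31)
  for (i in 1:10) {
    fa_grid <- seq(0.02, 0.98, length.out = 50)
    f1 <- median_effect_model(10^stats::runif(1, -1, 2),
                              stats::runif(1, 0.3, 5))
    f2 <- median_effect_model(10^stats::runif(1, -1, 2),
                              stats::runif(1, 0.3, 5))
    resid <- 3 / dose_for_effect(f1, fa_grid) +
      2 / dose_for_effect(f2, fa_grid)
    expect_true(all(diff(resid) < 0))
  }
  expect_error(loewe_effect(median_effect_model(10, 1),
                            structure(list(dm = 5, m = -1),
                                      class = "median_effect_fit"), 1, 1),
               "positive")
})

test_that("simulation is deterministic given config and seed", {
  cfg <- synthetic_config(seed = 99)
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))
  expect_identical(simulate_markers(cfg), simulate_markers(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  cfg2 <- synthetic_config(seed = 100)
  expect_false(identical(simulate_screen(cfg), simulate_screen(cfg2)))
})

test_that("noise-free single-agent output closes the median-effect loop", {
  cfg <- synthetic_config(drug_a = list(name = "A", dm = 37, m = 1.4),
                          noise_cv = 0, seed = 2)
  s <- build_series(simulate_single_agent(cfg, "a"))
  f <- fit_median_effect(s$A)
  expect_equal(f$dm, 37, tolerance = 1e-9)
  expect_equal(f$m, 1.4, tolerance = 1e-9)
  expect_equal(f$r, 1, tolerance = 1e-9)
})

test_that("per-dose sample CV lands near the configured CV", {
  cfg <- synthetic_config(noise_cv = 0.05, n_replicates = 30, seed = 4)
  w <- simulate_single_agent(cfg, "a")
  w <- w[w$dose_a > 0, ]
  cvs <- vapply(split(w$response, w$dose_a),
                function(v) stats::sd(v) / mean(v), 0)
  expect_true(all(cvs > 0.005 & cvs < 0.15))
})

test_that("Loewe-mode combinations are exactly additive (CI = 1)", {
  cfg <- synthetic_config(
    drug_a = list(name = "A", dm = 50, m = 2),
    drug_b = list(name = "B", dm = 5, m = 2),
    dose_grid_a = c(10, 25, 50, 75, 100),
    dose_grid_b = c(1, 2.5, 5, 7.5, 10),
    dose_grid_combo = c(11, 27.5, 55, 82.5, 110),
    interaction_mode = "loewe", noise_cv = 0, seed = 3)
  ser <- build_series(simulate_screen(cfg))
  lab <- fixture_combo_label(ser)
  curve <- fa_ci_curve(fit_median_effect(ser$A), fit_median_effect(ser$B),
                       fit_median_effect(ser[[lab]]),
                       ratio = ser[[lab]]$ratio)
  expect_true(all(abs(curve$ci - 1) < 1e-6))
})

test_that("Bliss-mode combinations have exactly zero Bliss deltas", {
  cfg <- synthetic_config(interaction_mode = "bliss", noise_cv = 0,
                          seed = 5)
  ser <- build_series(simulate_screen(cfg))
  tab <- synergy_table(ser$Q, ser$GEM, ser[[fixture_combo_label(ser)]])
  expect_equal(tab$delta_bliss, rep(0, nrow(tab)), tolerance = 1e-12)
})

test_that("potency-shift ground truth gives CI = 1/strength at every fa", {
  for (s in c(2, 4)) {
    cfg <- synthetic_config(
      drug_a = list(name = "A", dm = 50, m = 2),
      drug_b = list(name = "B", dm = 5, m = 2),
      dose_grid_a = c(10, 25, 50, 75, 100),
      dose_grid_b = c(1, 2.5, 5, 7.5, 10),
      dose_grid_combo = c(11, 27.5, 55, 82.5, 110),
      interaction_mode = "potency_shift", interaction_strength = s,
      noise_cv = 0, seed = 6)
    ser <- build_series(simulate_screen(cfg))
    lab <- fixture_combo_label(ser)
    curve <- fa_ci_curve(fit_median_effect(ser$A), fit_median_effect(ser$B),
                         fit_median_effect(ser[[lab]]),
                         ratio = ser[[lab]]$ratio)
    expect_true(all(abs(curve$ci - 1 / s) < 1e-6))
  }
})

test_that("marker and qPCR generators reproduce configured targets exactly", {
  cfg <- synthetic_config(noise_cv = 0, seed = 8)
  cfg$marker_spec <- lapply(cfg$marker_spec, function(m) {
    m$cv <- 0; m
  })
  mk <- simulate_markers(cfg)
  ros <- mk[mk$marker == "ROS", ]
  folds <- vapply(c("control", "Q", "GEM", "Q_GEM"), function(g)
    fold_change(ros$value[ros$group == g],
                ros$value[ros$group == "control"]), 0)
  expect_equal(unname(folds), c(1, 1.6, 2.4, 2.8))
  qp <- summarise_qpcr(simulate_qpcr(cfg))
  expect_equal(qp$rq[qp$target == "HIF1A" & qp$group == "Q_GEM"], 0.2)
  expect_equal(qp$rq[qp$target == "HIF1A" & qp$group == "Q"], 0.6)
})

test_that("config validation rejects out-of-contract settings", {
  expect_error(synthetic_config(noise_cv = 0.7), "noise_cv")
  expect_error(synthetic_config(interaction_strength = 0),
               "interaction_strength")
  expect_error(synthetic_config(dose_grid_a = c(5, 3)), "increasing")
})
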