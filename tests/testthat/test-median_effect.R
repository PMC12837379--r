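test_that("linearization maps to the log-odds plane and windows correctly", {
  pts <- linearize_median_effect(c(5, 1, 10), c(0.5, 0.3, 0.9))
  expect_equal(pts$log_odds[1], 0)                   # fa = fu at 0.5
  expect_equal(pts$log_dose[2], 0)                   # dose 1 µM
  expect_equal(pts$log_odds[3], log10(9))            # ~0.9542
  # window exclusions are reported with reasons
  pts2 <- linearize_median_effect(c(0, 5, 10, 20, 30),
                                  c(0, 0.005, 0.4, 0.5, 0.995))
  expect_equal(nrow(pts2), 2)
  ex <- attr(pts2, "excluded")
  expect_true("dose <= 0" %in% ex$reason)
  expect_true("fa below window" %in% ex$reason)
  expect_true("fa above window" %in% ex$reason)
  expect_error(linearize_median_effect(c(1, 2), c(0.999, 0.0001)),
               "insufficient")
})

test_that("noise-free median-effect data is recovered exactly", {
  doses <- c(2, 5, 10, 20, 50)
  fa <- (doses / 10)^2 / (1 + (doses / 10)^2)
  fit <- fit_median_effect(doses, fa)
  expect_equal(fit$dm, 10, tolerance = 1e-9)
  expect_equal(fit$m, 2, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  # property: exact recovery across the (dm, m) plane
  set.seed(7)
  for (i in 1:25) {
    dm <- 10^stats::runif(1, -1, 3)
    m <- stats::runif(1, 0.3, 5)
    d <- dm * 10^seq(-0.8, 0.8, length.out = 6)
    fa_i <- (d / dm)^m / (1 + (d / dm)^m)
    f <- fit_median_effect(d, fa_i)
    expect_equal(f$dm, dm, tolerance = 1e-8)
    expect_equal(f$m, m, tolerance = 1e-8)
  }
})

test_that("the packaged single-agent fits match the closed-form OLS oracle", {
  s <- fixture_series()
  fit_q <- fit_median_effect(s$Q)
  oq <- oracle_median_effect_ols(c(10, 20, 40, 80, 100),
                                 c(0.13, 0.18, 0.24, 0.44, 0.58))
  expect_equal(fit_q$dm, oq$dm, tolerance = 1e-12)
  expect_equal(fit_q$m, oq$m, tolerance = 1e-12)
  expect_equal(fit_q$r, oq$r, tolerance = 1e-12)
  # frozen oracle values (hand OLS on the 5 linearized points)
  expect_equal(fit_q$dm, 96.3494588, tolerance = 1e-7)
  expect_equal(fit_q$m, 0.9224870, tolerance = 1e-6)
  expect_equal(fit_q$r, 0.9630423, tolerance = 1e-6)
  fit_g <- fit_median_effect(s$GEM)
  expect_equal(fit_g$dm, 4.7872312, tolerance = 1e-7)
  expect_equal(fit_g$m, 0.8382195, tolerance = 1e-6)
})

test_that("single retained point is an insufficient-data error", {
  expect_error(fit_median_effect(c(0, 10), c(0, 0.5)), "insufficient")
})

test_that("dose_for_effect and effect_at_dose are exact inverses", {
  fit <- median_effect_model(10, 2)
  expect_equal(dose_for_effect(fit, 0.5), 10)
  expect_equal(dose_for_effect(median_effect_model(10, 1), 0.9), 90)
  expect_equal(effect_at_dose(fit, 10), 0.5)
  expect_equal(effect_at_dose(fit, 30), 0.9)     # (3^2)/(1+9)
  expect_equal(effect_at_dose(fit, dose_for_effect(fit, 0.37)), 0.37)
  expect_error(dose_for_effect(fit, 1), "inside")
  expect_error(effect_at_dose(fit, 0), "positive")
  # inverse identity across random fits and the (0.01, 0.99) range
  set.seed(11)
  for (i in 1:20) {
    f <- median_effect_model(10^stats::runif(1, -1, 3),
                             stats::runif(1, 0.3, 5))
    fa <- stats::runif(25, 0.01, 0.99)
    expect_equal(effect_at_dose(f, dose_for_effect(f, fa)), fa,
                 tolerance = 1e-9)
  }
})

test_that("sham combinations give CI = 1 and DRI equal to the inverse split", {
  set.seed(23)
  for (i in 1:20) {
    fit <- median_effect_model(10^stats::runif(1, -1, 3),
                               stats::runif(1, 0.3, 5))
    w <- stats::runif(1, 0.05, 0.95)
    for (fa in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      dx <- dose_for_effect(fit, fa)
      res <- combination_index(fit, fit, w * dx, (1 - w) * dx, fa)
      expect_equal(res$ci, 1, tolerance = 1e-6)
    }
    dx5 <- dose_for_effect(fit, 0.5)
    dri <- dose_reduction_index(fit, fit, dx5 / 2, dx5 / 2, 0.5)
    expect_equal(dri$dri_a, 2, tolerance = 1e-9)
    expect_equal(dri$dri_b, 2, tolerance = 1e-9)
  }
})

test_that("CI arithmetic and alpha behave per the defining equation", {
  fit_a <- median_effect_model(50, 1.2)
  fit_b <- median_effect_model(5, 0.9)
  fa <- 0.4
  dx1 <- dose_for_effect(fit_a, fa); dx2 <- dose_for_effect(fit_b, fa)
  res0 <- combination_index(fit_a, fit_b, 0.5 * dx1, 0.5 * dx2, fa,
                            alpha = 0)
  res1 <- combination_index(fit_a, fit_b, 0.5 * dx1, 0.5 * dx2, fa,
                            alpha = 1)
  expect_equal(res0$ci, 1)
  expect_equal(res1$ci, 1.25)            # 0.5 + 0.5 + 0.25
  # alpha = 1 never below alpha = 0; equality iff a component dose is 0
  res0z <- combination_index(fit_a, fit_b, 0, dx2, fa, alpha = 0)
  res1z <- combination_index(fit_a, fit_b, 0, dx2, fa, alpha = 1)
  expect_equal(res0z$ci, res1z$ci)
  expect_gt(res1$ci, res0$ci)
  # CI strictly decreasing in the reference doses: a more potent
  # single-agent curve (smaller Dx at same fa) raises CI
  expect_gt(combination_index(median_effect_model(25, 1.2), fit_b,
                              0.5 * dx1, 0.5 * dx2, fa)$ci, res0$ci)
})

test_that("CI at the observed Q80+GEM8 point matches the arithmetic oracle", {
  s <- fixture_series()
  fit_q <- fit_median_effect(s$Q)
  fit_g <- fit_median_effect(s$GEM)
  res <- combination_index(fit_q, fit_g, 80, 8, 0.62)
  oq <- oracle_median_effect_ols(c(10, 20, 40, 80, 100),
                                 c(0.13, 0.18, 0.24, 0.44, 0.58))
  og <- oracle_median_effect_ols(c(1, 2, 4, 8, 10),
                                 c(0.22, 0.34, 0.42, 0.54, 0.72))
  dx1 <- oq$dm * (0.62 / 0.38)^(1 / oq$m)
  dx2 <- og$dm * (0.62 / 0.38)^(1 / og$m)
  expect_equal(res$ci, 80 / dx1 + 8 / dx2, tolerance = 1e-12)
  expect_equal(res$ci, 1.420278, tolerance = 1e-6)   # frozen oracle value
  dri <- dose_reduction_index(fit_q, fit_g, 80, 8, 0.62)
  expect_equal(dri$dri_a, 2.047538, tolerance = 1e-6)
  expect_equal(dri$dri_b, 1.073092, tolerance = 1e-6)
  # a zero component dose has no defined DRI
  dri0 <- dose_reduction_index(fit_q, fit_g, 0, 8, 0.62)
  expect_true(is.na(dri0$dri_a))
})

test_that("the Fa-CI grid spans 0.25-0.90 by default and needs a grid", {
  fit <- median_effect_model(10, 1)
  curve <- fa_ci_curve(fit, fit, fit, ratio = c(1, 1))
  expect_equal(nrow(curve), 14)
  expect_equal(curve$fa[1], 0.25)
  expect_equal(curve$fa[14], 0.90)
  expect_true(all(diff(curve$fa) > 0))
  expect_error(fa_ci_curve(fit, fit, fit, ratio = c(1, 1),
                           grid = numeric(0)), "empty")
})

test_that("stochastic recovery at plate-realistic noise stays within bounds", {
  # CV = 5%, n = 3, 6 doses, 50 seeded repetitions
  errs <- vapply(1:50, function(s) {
    cfg <- synthetic_config(
      drug_a = list(name = "A", dm = 50, m = 2),
      dose_grid_a = c(5, 15, 35, 60, 85, 110),
      dose_grid_b = c(1, 2, 4, 8, 10, 12),
      noise_cv = 0.05, n_replicates = 3, seed = 1000 + s)
    sr <- build_series(simulate_single_agent(cfg, "a"))
    f <- fit_median_effect(sr$A)
    c(abs(f$dm / 50 - 1), abs(f$m / 2 - 1))
  }, c(0, 0))
  expect_lt(stats::median(errs[1, ]), 0.15)
  expect_lt(stats::median(errs[2, ]), 0.20)
})
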