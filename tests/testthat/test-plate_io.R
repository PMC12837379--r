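test_that("well tables round-trip and validate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("agent_a,dose_a,agent_b,dose_b,replicate,response,response_kind",
               "Q,10,,0,1,85,percent_viability",
               "Q,20,,0,1,71,percent_viability"), tmp)
  w <- read_well_table(tmp)
  expect_s3_class(w, "well_table")
  expect_equal(nrow(w), 2)
  expect_equal(w$dose_a, c(10, 20))
  expect_equal(w$response, c(85, 71))
})

test_that("the packaged screen has 16 conditions in triplicate", {
  w <- read_well_table(example_data_path("viability"))
  expect_equal(nrow(w), 48)
  cond <- unique(paste(w$agent_a, w$dose_a, w$agent_b, w$dose_b))
  expect_length(cond, 16)
})

test_that("format errors are specific", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("agent_a,agent_b,dose_b,replicate,response,response_kind",
               "Q,,0,1,85,percent_viability"), tmp)
  expect_error(read_well_table(tmp), "dose_a")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("agent_a,dose_a,agent_b,dose_b,replicate,response,response_kind",
               "Q,ten,,0,1,85,percent_viability"), tmp2)
  expect_error(read_well_table(tmp2), "row 1")

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("agent_a,dose_a,agent_b,dose_b,replicate,response,response_kind",
               "Q,10,,0,1,85,absorbance_maybe"), tmp3)
  expect_error(read_well_table(tmp3), "response_kind")
})

test_that("raw signals normalise to percent of mean control", {
  w <- well_table(agent_a = c("control", "control", "Q", "Q"),
                  dose_a = c(0, 0, 10, 10), replicate = c(1, 2, 1, 2),
                  response = c(0.8, 1.2, 0.4, 0.6),
                  response_kind = "raw_signal")
  s <- build_series(w)
  expect_equal(s$Q$data$mean_viability, c(100, 50))
  # control-only table: single self-normalised series at dose 0
  ctl <- well_table(agent_a = "control", dose_a = 0, replicate = 1:3,
                    response = c(0.9, 1.0, 1.1),
                    response_kind = "raw_signal")
  s2 <- build_series(ctl)
  expect_length(s2, 1)
  expect_equal(s2[[1]]$data$mean_viability, 100)
  # raw signals without controls refuse to normalise
  noctl <- well_table(agent_a = "Q", dose_a = c(10, 20), replicate = 1,
                      response = c(0.4, 0.2), response_kind = "raw_signal")
  expect_error(build_series(noctl), "control")
})

test_that("percent viability passes through unchanged and combos key by total dose", {
  s <- fixture_series()
  expect_equal(s$Q$data$mean_viability, c(98, 87, 82, 76, 56, 42))
  expect_equal(s$GEM$data$mean_viability, c(98, 78, 66, 58, 46, 28))
  combo <- s[[fixture_combo_label(s)]]
  expect_equal(combo$data$total_dose, c(0, 11, 22, 44, 88, 110))
  expect_equal(unname(combo$ratio[["Q"]]), 10 / 11)
  expect_equal(unname(combo$ratio[["GEM"]]), 1 / 11)
})

test_that("series building is invariant to row permutation", {
  w <- read_well_table(example_data_path("viability"))
  set.seed(42)
  w2 <- w[sample(nrow(w)), ]
  rownames(w2) <- NULL
  s1 <- build_series(w)
  s2 <- build_series(w2)
  expect_equal(s1, s2)
})

test_that("inconsistent combination ratios are a grouping error", {
  w <- well_table(agent_a = c("A", "A"), dose_a = c(10, 10),
                  agent_b = c("B", "B"), dose_b = c(1, 5), replicate = 1,
                  response = c(50, 40))
  # same unordered pair, two different ratios -> two distinct series
  s <- build_series(w)
  expect_length(s, 2)
  # but the same nominal ratio perturbed only in the 7th digit stays one
  w2 <- well_table(agent_a = c("A", "A"), dose_a = c(10, 20.0000004),
                   agent_b = c("B", "B"), dose_b = c(1, 2), replicate = 1,
                   response = c(50, 40))
  expect_length(build_series(w2), 1)
})

test_that("config loading merges defaults and warns on unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synergy:", "  alpha: 1", "  made_up_key: 3"), tmp)
  expect_warning(cfg <- load_config(tmp), "made_up_key")
  expect_equal(cfg$synergy$alpha, 1)
  expect_equal(cfg$synergy$fa_min, 0.25)  # default preserved
  # empty file -> pure defaults
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp2)
  expect_equal(load_config(tmp2), default_config())
})

test_that("JSON reports round-trip losslessly and byte-stably", {
  res <- list(fits = list(Q = list(dm = 96.3494588, m = 0.9224870)),
              grid = data.frame(fa = c(0.25, 0.5), ci = c(1.1, 0.9)))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(res, p1)
  write_report(res, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  expect_equal(back$fits$Q$dm, 96.3494588)
  expect_equal(back$grid$ci, c(1.1, 0.9))
})
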