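test_that("identical parameters reproduce the cohort exactly", {
  p <- sim_params(n_users = 40, seed = 99)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$records, b$records)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)
})

test_that("zero step scale yields exactly constant low-class series", {
  co <- simulate_cohort(sim_params(n_users = 60, step_scale_low = 0,
                                   step_scale_high = 2, seed = 5))
  vol <- window_volatility(co$records)
  planted <- tidyr::pivot_longer(co$truth, -user_id,
                                 names_to = "window", values_to = "class",
                                 names_prefix = "class_")
  joined <- dplyr::inner_join(vol, planted, by = c("user_id", "window"))
  low <- joined[joined$class == "low", ]
  expect_gt(nrow(low), 0)
  expect_true(all(low$volatility == 0))
})

test_that("planted classes separate in empirical volatility", {
  co <- simulate_cohort(sim_params(n_users = 600, prop_high = 0.21,
                                   step_scale_low = 0.5,
                                   step_scale_high = 2.5, seed = 17))
  vol <- window_volatility(co$records)
  vol <- vol[vol$window == "predictor", ]
  joined <- dplyr::inner_join(vol, co$truth, by = "user_id")
  m_low <- mean(joined$volatility[joined$class_predictor == "low"])
  m_high <- mean(joined$volatility[joined$class_predictor == "high"])
  expect_gt(m_high, m_low)
  # E|step| equals the step scale before boundary reflection; reflection
  # into [0, 10] dampens the large-step class, so the recovered gap sits
  # between 3x and the planted 5x ratio.
  expect_gt(m_high / m_low, 3)
  expect_lt(m_high / m_low, 5.5)
  expect_equal(m_low, 0.5, tolerance = 0.15)
})

test_that("class persistence is recovered from the planted truth", {
  p_target <- 0.8
  co <- simulate_cohort(sim_params(n_users = 1500,
                                   class_persistence = p_target,
                                   seed = 31))
  frac <- mean(co$truth$class_predictor == co$truth$class_outcome)
  expect_equal(frac, p_target, tolerance = 0.03)
})

test_that("record dates fall only in the two 30-day windows", {
  co <- simulate_cohort(sim_params(n_users = 50, seed = 8))
  rec <- assign_windows(co$records)
  expect_true(all(!is.na(rec$window)))
  expect_true(all(rec$day %in% c(0:29, 150:179)))
  counts <- dplyr::count(rec, user_id, window)
  expect_true(all(counts$n >= 2 & counts$n <= 30))
})

test_that("informative descriptors shift occurrence between classes", {
  co <- simulate_cohort(sim_params(n_users = 800,
                                   n_informative_descriptors = 2,
                                   descriptor_effect = 0.15, seed = 12))
  rec <- assign_windows(co$records)
  rec <- rec[rec$window == "predictor", ]
  joined <- dplyr::inner_join(rec, co$truth, by = "user_id")
  rate <- function(cl) {
    rows <- joined[joined$class_predictor == cl, ]
    mean(grepl("\\bhead\\b", rows$locations))
  }
  expect_gt(rate("high"), rate("low") + 0.05)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(prop_high = 0), class = "painvol_config_error")
  expect_error(sim_params(prop_high = 1.2), class = "painvol_config_error")
  expect_error(sim_params(step_scale_low = 2, step_scale_high = 1),
               class = "painvol_config_error")
  expect_error(sim_params(class_persistence = 1.5),
               class = "painvol_config_error")
  expect_error(sim_params(records_per_window_mean = 0),
               class = "painvol_config_error")
  expect_error(sim_params(n_users = 2.5), class = "painvol_config_error")
  expect_error(simulate_cohort(list(n_users = 5)),
               class = "painvol_config_error")
})

test_that("cohort files round-trip through the delimited format", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$profiles, co$profiles)
  expect_equal(as.data.frame(back$records), as.data.frame(co$records))
})

test_that("malformed or out-of-range rows are rejected with a row number", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_params(n_users = 5, seed = 2))
  bad <- co
  bad$records$severity[3] <- 11
  write_cohort(bad, dir)
  expect_error(read_cohort(dir), "row 3.*11",
               class = "painvol_validation_error")

  bad$records$severity[3] <- NA
  write_cohort(bad, dir)
  expect_error(read_cohort(dir), "row 3",
               class = "painvol_parse_error")
})

test_that("an empty records file yields an empty cohort without error", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_params(n_users = 5, seed = 2))
  co$records <- co$records[0, ]
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$records), 0)
  expect_equal(nrow(back$profiles), 5)
})
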