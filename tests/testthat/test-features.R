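test_that("volatility matches its defining formula on fixed examples", {
  expect_equal(compute_volatility(c(3, 3, 3, 3)), 0)
  expect_equal(compute_volatility(c(2, 5, 3)), 2.5)
  expect_equal(compute_volatility(c(0, 10, 0, 10, 0)), 10)
  expect_error(compute_volatility(c(4)),
               class = "painvol_undefined_volatility")
  expect_error(compute_volatility(c(1, NA, 2)),
               class = "painvol_validation_error")
})

test_that("volatility is translation-invariant and scales linearly", {
  withr::with_seed(7, {
    for (i in 1:50) {
      x <- runif(sample(2:15, 1), 0, 10)
      v <- compute_volatility(x)
      expect_equal(compute_volatility(x + 0.37), v)
      expect_equal(compute_volatility(x * 2.5), v * 2.5)
    }
  })
})

test_that("trend delta equals the OLS endpoint difference", {
  expect_equal(trend_delta(1:5, 1:5), list(delta = 4, abs_delta = 4))
  expect_equal(trend_delta(1:6, rep(3, 6)), list(delta = 0, abs_delta = 0))
  expect_equal(trend_delta(c(0, 10), c(5, 1)),
               list(delta = -4, abs_delta = 4))
  expect_error(trend_delta(c(2, 2, 2), c(1, 2, 3)),
               class = "painvol_degenerate_fit")
  expect_error(trend_delta(1:3, 1:2), class = "painvol_validation_error")
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(3:12, 1)
      t <- sort(sample(0:29, n))
      r <- runif(n, 0, 10)
      expect_equal(trend_delta(t, r), oracle_trend(t, r), tolerance = 1e-10)
    }
  })
})

test_that("the inclusion filter requires enough records in both windows", {
  rec <- dplyr::bind_rows(
    make_records("both_ok", c(0:4, 150:154), 5),
    make_records("few_pred", c(0:3, 150:169), 5),
    make_records("few_out", c(0:19, 150:153), 5),
    make_records("boundary", c(0:4, 150:154), 5))
  kept <- filter_users(rec, min_records = 5)
  expect_setequal(kept$user_id, c("both_ok", "boundary"))
  expect_equal(kept$n_predictor[kept$user_id == "both_ok"], 5L)
})

test_that("filter counts match direct enumeration on a planted cohort", {
  # 90 users with >= 5 records per window, 10 forced below threshold.
  rec <- purrr::map_dfr(1:100, function(i) {
    n <- if (i <= 10) 3L else 8L
    make_records(sprintf("u%03d", i), c(seq_len(n) - 1L, 150:157),
                 runif(n + 8, 0, 10))
  })
  expect_equal(nrow(filter_users(rec, 5)), 90L)
})

test_that("feature vectors have 132 schema-ordered, complete entries", {
  schema <- feature_schema()
  expect_equal(nrow(schema), 132L)
  counts <- dplyr::count(schema, category)
  expect_equal(
    tibble::deframe(counts)[c("demographic", "app_usage", "pain_statistics",
                              "pain_descriptors", "factors", "conditions",
                              "medications", "mental_health")],
    c(demographic = 2L, app_usage = 2L, pain_statistics = 8L,
      pain_descriptors = 64L, factors = 43L, conditions = 6L,
      medications = 5L, mental_health = 2L))

  co <- small_cohort()
  el <- filter_users(co$records)
  fe <- extract_features(co$records, co$profiles, users = el$user_id,
                         volatility_threshold = 1.6)
  expect_equal(names(fe), c("user_id", schema$feature))
  expect_equal(nrow(fe), nrow(el))
  expect_false(anyNA(fe))
})

test_that("app-usage slots count records and distinct days", {
  rec <- dplyr::bind_rows(
    make_records("u1", c(0, 0, 1, 2, 2, 3, 4), c(1, 2, 3, 4, 5, 6, 7)),
    make_records("u1", 150:154, rep(5, 5)))
  fe <- extract_features(rec, make_profile("u1"),
                         volatility_threshold = 1.6)
  expect_equal(fe$n_records, 7)
  expect_equal(fe$n_days, 5)
})

test_that("a constant-severity user zeroes the pain-statistics block", {
  rec <- dplyr::bind_rows(make_records("u1", 0:6, rep(4, 7)),
                          make_records("u1", 150:155, rep(4, 6)))
  fe <- extract_features(rec, make_profile("u1"),
                         volatility_threshold = 1.6,
                         severity_threshold = 5)
  expect_equal(
    unlist(fe[, c("severity_mean", "severity_sd", "abs_change_mean",
                  "abs_change_sd", "trend_delta", "trend_abs_delta",
                  "severity_level", "volatility_level")]),
    c(severity_mean = 4, severity_sd = 0, abs_change_mean = 0,
      abs_change_sd = 0, trend_delta = 0, trend_abs_delta = 0,
      severity_level = 0, volatility_level = 0))
})

test_that("level features dichotomize at the supplied thresholds", {
  rec <- dplyr::bind_rows(
    make_records("calm", 0:5, c(2, 2.2, 2, 2.1, 2, 2.2)),
    make_records("calm", 150:154, rep(2, 5)),
    make_records("volatile", 0:5, c(1, 8, 1, 8, 1, 8)),
    make_records("volatile", 150:154, rep(5, 5)))
  fe <- extract_features(rec, dplyr::bind_rows(make_profile("calm"),
                                               make_profile("volatile")),
                         volatility_threshold = 1.6,
                         severity_threshold = 4)
  fe <- fe[order(fe$user_id), ]
  expect_equal(fe$volatility_level, c(0, 1))
  expect_equal(fe$severity_level, c(0, 1))
})

test_that("descriptor presence is binary over the window", {
  rec <- dplyr::bind_rows(
    make_records("u1", 0:4, 5, locations = c("head;neck", "head", "", "", ""),
                 symptoms = c("", "", "fatigue", "", "")),
    make_records("u1", 150:154, 5, locations = "", symptoms = ""))
  prof <- make_profile("u1", conditions = "migraine",
                       mental_health = "anxiety")
  fe <- extract_features(rec, prof, volatility_threshold = 1.6)
  expect_equal(fe$location_head, 1)
  expect_equal(fe$location_neck, 1)
  expect_equal(fe$symptom_fatigue, 1)
  expect_equal(fe$location_jaw, 0)
  expect_equal(fe$condition_migraine, 1)
  expect_equal(fe$mental_health_anxiety, 1)
  expect_equal(fe$mental_health_depression, 0)
})

test_that("unknown descriptor tokens are dropped with a warning", {
  rec <- dplyr::bind_rows(
    make_records("u1", 0:4, 5, locations = c("head;xyzzy", "", "", "", "")),
    make_records("u1", 150:154, 5, locations = ""))
  expect_warning(
    fe <- extract_features(rec, make_profile("u1"),
                           volatility_threshold = 1.6),
    "xyzzy")
  expect_equal(fe$location_head, 1)
})

test_that("missing demographics are imputed, missing profiles are fatal", {
  rec <- purrr::map_dfr(c("u1", "u2", "u3"), function(u)
    dplyr::bind_rows(make_records(u, 0:5, runif(6, 0, 10)),
                     make_records(u, 150:155, runif(6, 0, 10))))
  prof <- dplyr::bind_rows(
    make_profile("u1", age = 30L, gender = "male"),
    make_profile("u2", age = 50L, gender = NA_character_),
    make_profile("u3", age = NA_integer_))
  fe <- extract_features(rec, prof, volatility_threshold = 1.6)
  fe <- fe[order(fe$user_id), ]
  expect_equal(fe$age, c(30, 50, 40))   # median of 30, 50
  expect_equal(fe$gender, c(0, 0.5, 1))
  expect_error(
    extract_features(rec, prof[1:2, ], volatility_threshold = 1.6),
    "u3", class = "painvol_validation_error")
})

test_that("extraction is deterministic given identical inputs", {
  co <- small_cohort()
  el <- filter_users(co$records)
  a <- extract_features(co$records, co$profiles, users = el$user_id,
                        volatility_threshold = 1.6)
  b <- extract_features(co$records, co$profiles, users = el$user_id,
                        volatility_threshold = 1.6)
  expect_identical(a, b)
})
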