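test_that("information gain matches direct entropy arithmetic", {
  y <- rep(c("low", "high"), each = 4)
  expect_equal(information_gain(as.numeric(y == "high"), y), 1)

  # 8 samples, balanced outcome, feature splitting (3 low, 1 high) vs
  # (1 low, 3 high): IG = 1 - H(1/4) = 0.18872 bits
  x <- rep(c(0, 1), each = 4)
  y2 <- c("low", "low", "low", "high", "low", "high", "high", "high")
  h_quarter <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(information_gain(x, y2), 1 - h_quarter, tolerance = 1e-10)
  expect_equal(information_gain(x, y2), oracle_info_gain(x, y2))

  withr::with_seed(5, {
    for (i in 1:40) {
      n <- sample(20:80, 1)
      xf <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
      yf <- sample(c("low", "high"), n, replace = TRUE)
      expect_equal(information_gain(xf, yf), oracle_info_gain(xf, yf),
                   tolerance = 1e-12)
      expect_gte(information_gain(xf, yf), 0)
      expect_lte(information_gain(xf, yf),
                 oracle_entropy_bits(table(yf)) + 1e-12)
    }
  })
})

test_that("information gain of an independent feature is near zero", {
  withr::with_seed(21, {
    x <- rnorm(500)
    y <- sample(c("low", "high"), 500, replace = TRUE)
  })
  expect_lt(information_gain(x, y), 0.02)
})

test_that("single-class labels give zero gain with a warning", {
  expect_warning(ig <- information_gain(1:10, rep("low", 10)),
                 "single class")
  expect_equal(ig, 0)
})

test_that("a perfect stump credits its split feature with 0.5", {
  xs <- data.frame(a = rep(c(0, 1), each = 4), b = rep(c(0, 1), 4))
  ys <- rep(c("low", "high"), each = 4)
  fit <- withr::with_seed(1, randomForest::randomForest(
    x = xs, y = factor(ys, c("low", "high")), ntree = 1, mtry = 2,
    maxnodes = 2, replace = FALSE, sampsize = 8, keep.inbag = TRUE,
    keep.forest = TRUE))
  g <- gini_importance(fit, xs, ys)
  expect_equal(g$importance[g$feature == "a"], 0.5)
  expect_equal(g$importance[g$feature == "b"], 0)
})

test_that("gini importance reproduces the forest's recorded scores", {
  withr::with_seed(4, {
    n <- 150
    x <- as.data.frame(matrix(rnorm(n * 10), n))
    names(x) <- sprintf("f%02d", 1:10)
    y <- ifelse(x$f01 + 0.5 * x$f02 + rnorm(n, 0, 0.8) > 0, "high", "low")
  })
  m <- train_rf(x, y, n_trees = 30, seed = 7)
  g <- gini_importance(m, x, y)
  ref <- m$fit$importance[, "MeanDecreaseGini"]
  mine <- g$importance[match(names(ref), g$feature)] * n
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  expect_true(all(g$importance >= 0))
})

test_that("per-feature importances sum to the forest's impurity decrease", {
  withr::with_seed(9, {
    n <- 120
    x <- as.data.frame(matrix(rnorm(n * 8), n))
    names(x) <- sprintf("f%02d", 1:8)
    x$dead <- 1   # constant: never splittable
    y <- ifelse(x$f01 > 0, "high", "low")
  })
  m <- train_rf(x, y, n_trees = 25, seed = 3)
  g <- gini_importance(m, x, y)
  expect_equal(g$importance[g$feature == "dead"], 0)
  total_recorded <- sum(m$fit$importance[, "MeanDecreaseGini"]) / n
  expect_equal(sum(g$importance), total_recorded, tolerance = 1e-10)
})

test_that("a planted feature dominates the Gini ranking", {
  first <- 0L
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- 200
      x <- as.data.frame(matrix(rnorm(n * 20), n))
      names(x) <- sprintf("f%02d", 1:20)
      y <- ifelse(x$f07 + rnorm(n, 0, 0.5) > 0, "high", "low")
    })
    m <- train_rf(x, y, n_trees = 50, seed = s)
    g <- gini_importance(m, x, y)
    if (g$feature[1] == "f07") first <- first + 1L
  }
  expect_gte(first, 4L)
})

test_that("boruta confirms a label copy and rejects pure noise", {
  withr::with_seed(33, {
    n <- 200
    x <- as.data.frame(matrix(rnorm(n * 8), n))
    names(x) <- sprintf("noise%02d", 1:8)
    y <- sample(c("low", "high"), n, replace = TRUE)
    x$copy <- as.numeric(y == "high")
  })
  b <- boruta(x, y, max_iter = 40, seed = 2)
  d <- b$decisions
  expect_equal(d$status[d$feature == "copy"], "important")
  expect_false(any(d$status[d$feature != "copy"] == "important"))
  expect_true(all(d$hits <= d$runs))
  expect_setequal(d$feature, names(x))
})

test_that("too few iterations leave every feature tentative", {
  withr::with_seed(12, {
    x <- as.data.frame(matrix(rnorm(100 * 5), 100))
    y <- sample(c("low", "high"), 100, replace = TRUE)
  })
  b <- boruta(x, y, max_iter = 5, seed = 1)
  expect_true(all(b$decisions$status == "tentative"))
  expect_equal(b$iterations, 5L)
})

test_that("boruta input validation", {
  y <- rep(c("low", "high"), 10)
  expect_error(boruta(data.frame(a = rnorm(20)), y),
               class = "painvol_validation_error")
  expect_error(boruta(data.frame(a = rnorm(20), b = rnorm(20)), y,
                      max_iter = 3),
               class = "painvol_config_error")
  expect_error(
    boruta(data.frame(a = rnorm(20), b = rnorm(20)), y,
           importance_fn = function(d, l, s)
             stats::setNames(rep(NaN, ncol(d)), colnames(d))),
    class = "painvol_validation_error")
})

test_that("consensus is the union of per-method intersections", {
  co <- simulate_cohort(sim_params(n_users = 250, step_scale_low = 0.5,
                                   step_scale_high = 2.5, seed = 61))
  rec <- assign_windows(co$records)
  el <- filter_users(rec)
  vol <- window_volatility(rec)
  vol <- vol[vol$user_id %in% el$user_id, ]
  lab <- label_volatility(vol, seed = 1)
  fe <- extract_features(rec, co$profiles, users = el$user_id,
                         volatility_threshold = lab$threshold)
  out <- dplyr::transmute(
    dplyr::filter(tidy(lab), window == "outcome"),
    user_id, class = as.character(class))
  folds <- stratified_kfold(out, k = 2, seed = 2)
  grid <- build_training_grid(folds, n_subsamples = 2, seed = 3)
  cs <- suppressWarnings(
    consensus_select(fe, out, grid, n_trees = 25, boruta_max_iter = 15,
                     seed = 4))

  expect_setequal(cs$selected,
                  unique(unlist(cs$per_method, use.names = FALSE)))
  # each per-method intersection is contained in every per-set top list
  rk <- cs$rankings
  for (i in unique(rk$set_id)) {
    top_g <- rk$feature[rk$set_id == i & rk$method == "gini" & rk$rank <= 11]
    expect_true(all(cs$per_method$gini %in% top_g))
    top_i <- rk$feature[rk$set_id == i & rk$method == "info_gain" &
                          rk$rank <= 8]
    expect_true(all(cs$per_method$info_gain %in% top_i))
  }
  for (i in unique(cs$boruta$set_id)) {
    imp <- cs$boruta$feature[cs$boruta$set_id == i &
                               cs$boruta$status == "important"]
    expect_true(all(cs$per_method$boruta %in% imp))
  }
  # order of schema, not discovery, defines the reported sequence
  expect_equal(cs$selected,
               intersect(setdiff(names(fe), "user_id"), cs$selected))

  cs2 <- suppressWarnings(
    consensus_select(fe, out, grid, n_trees = 25, boruta_max_iter = 15,
                     seed = 4))
  expect_identical(cs$selected, cs2$selected)

  # order-invariance: permuting the grid rows changes nothing
  perm <- grid[c(3, 1, 4, 2), ]
  cs3 <- suppressWarnings(
    consensus_select(fe, out, perm, n_trees = 25, boruta_max_iter = 15,
                     seed = 4))
  expect_identical(cs$selected, cs3$selected)
  expect_identical(cs$per_method, cs3$per_method)
})

test_that("the elbow rule cuts at the largest relative drop", {
  expect_equal(painvol:::elbow_cut(c(10, 9.5, 9, 2, 1.9, 1.8, 1.7)), 3L)
  expect_equal(painvol:::elbow_cut(c(5, 1, 0.9, 0.8)), 1L)
})
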