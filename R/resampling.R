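#' Stratified k-fold assignment
#'
#' Assigns each user to exactly one test fold such that fold sizes differ by
#' at most one and each fold's class composition matches the overall class
#' proportions to within one user per class.
#'
#' @param data A tibble with `user_id` and `class` columns (`"low"` /
#'   `"high"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return `data` with an added integer `fold` column (a `pv_folds` tibble).
#' @export
stratified_kfold <- function(data, k = 5L, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  if (!all(c("user_id", "class") %in% names(data))) {
    abort("`data` must have `user_id` and `class` columns.",
          class = "painvol_validation_error")
  }
  cls <- class_factor(data$class)
  if (anyNA(cls)) {
    abort("`class` must contain only \"low\" and \"high\".",
          class = "painvol_validation_error")
  }
  counts <- table(cls)
  if (any(counts < k)) {
    abort(sprintf("Every class needs at least k = %d members.", k),
          class = "painvol_validation_error")
  }
  fold <- integer(nrow(data))
  offset <- 0L
  withr::with_seed(seed, {
    for (cl in levels(cls)) {
      idx <- sample(which(cls == cl))
      # Deal shuffled users to folds cyclically; rotate the dealing origin
      # between classes so leftover users spread across different folds and
      # overall fold sizes stay within one of each other.
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  out <- mutate(as_tibble(data), fold = fold)
  class(out) <- c("pv_folds", class(out))
  out
}

#' Balance a training set by random under-sampling
#'
#' Keeps every minority-class user and a uniform random subset (without
#' replacement) of majority-class users of the same size, so both classes
#' are equally represented.
#'
#' @param data A tibble with `user_id` and `class` columns.
#' @param seed Integer seed.
#' @return The balanced subset of `data` rows (minority class first).
#' @export
random_undersample <- function(data, seed = 1L) {
  cls <- class_factor(data$class)
  counts <- table(cls)
  if (any(counts == 0L)) {
    abort("Both classes must be present to under-sample.",
          class = "painvol_validation_error")
  }
  minority <- names(counts)[which.min(counts)]
  keep_min <- which(cls == minority)
  maj_idx <- which(cls != minority)
  keep_maj <- withr::with_seed(seed,
                               sample(maj_idx, length(keep_min),
                                      replace = FALSE))
  as_tibble(data)[c(keep_min, sort(keep_maj)), , drop = FALSE]
}

#' Build the grid of balanced training sets
#'
#' For each of the `k` cross-validation folds, repeats random
#' under-sampling `n_subsamples` times on the fold's training portion
#' (all users outside the test fold), yielding `k * n_subsamples` balanced
#' training sets — 25 with the defaults. Evaluation later uses the full,
#' untouched test fold, so reported denominators are whole class sizes.
#'
#' Child seeds are derived deterministically from `seed` per
#' (fold, subsample) cell, so one integer reproduces the whole grid.
#'
#' @param folds A `pv_folds` tibble from [stratified_kfold()].
#' @param n_subsamples Number of under-sampling repetitions per fold.
#' @param seed Master integer seed.
#' @return A `pv_grid` tibble: one row per (fold, subsample) with the child
#'   `seed` and a `users` list-column of balanced training user ids.
#' @export
build_training_grid <- function(folds, n_subsamples = 5L, seed = 1L) {
  n_subsamples <- assert_count(n_subsamples, "n_subsamples")
  if (!all(c("user_id", "class", "fold") %in% names(folds))) {
    abort("`folds` must come from stratified_kfold().",
          class = "painvol_validation_error")
  }
  k <- max(folds$fold)
  grid <- tidyr::expand_grid(fold = seq_len(k),
                             subsample = seq_len(n_subsamples))
  grid$seed <- derive_seeds(seed, nrow(grid))
  grid$users <- purrr::pmap(grid, function(fold, subsample, seed) {
    train <- folds[folds$fold != fold, c("user_id", "class")]
    random_undersample(train, seed = seed)$user_id
  })
  class(grid) <- c("pv_grid", class(grid))
  attr(grid, "k") <- k
  attr(grid, "n_subsamples") <- n_subsamples
  grid
}

# Leakage guard: no training set may contain a user from its own test fold.
check_no_leakage <- function(grid, folds) {
  for (i in seq_len(nrow(grid))) {
    test_users <- folds$user_id[folds$fold == grid$fold[i]]
    if (length(intersect(grid$users[[i]], test_users)) > 0L) {
      return(FALSE)
    }
  }
  TRUE
}
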