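#' Low/high volatility boundary by 1-D k-means
#'
#' Splits pooled volatility values into two clusters by k-means (k = 2,
#' `n_init` restarts, best within-cluster sum of squares kept) and defines
#' the class boundary as the midpoint between the largest value of the low
#' cluster and the smallest value of the high cluster. Every value below the
#' threshold is labeled `"low"`, every value at or above it `"high"`, which
#' is exactly consistent with the optimal clustering because 1-D k-means
#' clusters are intervals.
#'
#' In the intended use the input pools each user's predictor-window and
#' outcome-window volatility (two values per user) and the same threshold is
#' applied to both windows; see [label_volatility()].
#'
#' @param values Numeric vector of volatility values (at least 2 distinct).
#' @param seed Integer seed for the k-means restarts.
#' @param n_init Number of random restarts (default 25).
#' @return A `pv_labeling` object: `threshold`, sorted `centroids`,
#'   `classes` (factor aligned with `values`), and the input `values`.
#' @examples
#' km <- kmeans_threshold(c(rep(0.1, 50), rep(5, 50)))
#' km$threshold   # 2.55
#' @export
kmeans_threshold <- function(values, seed = 1L, n_init = 25L) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be a finite numeric vector.",
          class = "painvol_validation_error")
  }
  n_init <- assert_count(n_init, "n_init")
  if (length(unique(values)) < 2L) {
    abort("All volatility values are identical; a 2-class split is undefined.",
          class = "painvol_degenerate_clustering")
  }
  km <- withr::with_seed(seed,
                         kmeans(values, centers = 2L, nstart = n_init))
  low_cluster <- which.min(km$centers)
  threshold <- (max(values[km$cluster == low_cluster]) +
                  min(values[km$cluster != low_cluster])) / 2
  classes <- class_factor(ifelse(values < threshold, "low", "high"))
  structure(
    list(threshold = threshold,
         centroids = sort(as.numeric(km$centers)),
         classes = classes,
         values = values,
         tot_withinss = km$tot.withinss),
    class = "pv_labeling")
}

#' @export
print.pv_labeling <- function(x, ...) {
  cat(sprintf(
    "<pv_labeling> threshold %.3f (centroids %.3f / %.3f); %d low, %d high\n",
    x$threshold, x$centroids[1L], x$centroids[2L],
    sum(x$classes == "low"), sum(x$classes == "high")))
  invisible(x)
}

#' Label per-user, per-window volatility classes
#'
#' Pools the volatility values of both observation windows, derives one
#' threshold with [kmeans_threshold()], and applies it to every
#' (user, window) pair.
#'
#' @param volatility A tibble from [window_volatility()] (columns `user_id`,
#'   `window`, `volatility`), restricted to the users of interest.
#' @inheritParams kmeans_threshold
#' @return A `pv_labeling` whose `assignments` tibble has columns
#'   `user_id`, `window`, `volatility`, `class`.
#' @export
label_volatility <- function(volatility, seed = 1L, n_init = 25L) {
  needed <- c("user_id", "window", "volatility")
  if (!all(needed %in% names(volatility))) {
    abort("`volatility` must have user_id, window and volatility columns.",
          class = "painvol_validation_error")
  }
  if (anyNA(volatility$volatility)) {
    abort("Undefined volatility values present; filter users first.",
          class = "painvol_undefined_volatility")
  }
  lab <- kmeans_threshold(volatility$volatility, seed = seed, n_init = n_init)
  lab$assignments <- volatility |>
    select("user_id", "window", "volatility") |>
    mutate(class = lab$classes)
  lab
}

#' @export
tidy.pv_labeling <- function(x, ...) {
  if (!is.null(x$assignments)) return(x$assignments)
  tibble(value = x$values, class = x$classes)
}

#' @export
glance.pv_labeling <- function(x, ...) {
  tibble(threshold = x$threshold,
         centroid_low = x$centroids[1L],
         centroid_high = x$centroids[2L],
         n = length(x$classes),
         n_low = sum(x$classes == "low"),
         n_high = sum(x$classes == "high"),
         tot_withinss = x$tot_withinss)
}

#' Threshold stability over random subsamples
#'
#' Re-runs [kmeans_threshold()] on `n_subsamples` random subsets holding a
#' fraction `frac` of the pooled volatility values and summarises the spread
#' of the resulting thresholds. A stable bimodal population yields
#' thresholds tightly concentrated inside the between-mode gap.
#'
#' @inheritParams kmeans_threshold
#' @param n_subsamples Number of random subsamples.
#' @param frac Fraction of values kept per subsample, in (0, 1].
#' @return A list with `thresholds` (tibble `subsample`, `n`, `threshold`)
#'   and `summary` (tibble `mean`, `sd`, `min`, `max`, `n_skipped`).
#' @export
validate_threshold <- function(values, n_subsamples = 20L, frac = 0.5,
                               seed = 1L, n_init = 25L) {
  n_subsamples <- assert_count(n_subsamples, "n_subsamples")
  assert_scalar_number(frac, "frac")
  if (frac <= 0 || frac > 1) {
    abort("`frac` must lie in (0, 1].", class = "painvol_config_error")
  }
  seeds <- derive_seeds(seed, 2L * n_subsamples)
  size <- max(2L, floor(frac * length(values)))
  rows <- vector("list", n_subsamples)
  n_skipped <- 0L
  for (i in seq_len(n_subsamples)) {
    sub <- withr::with_seed(seeds[i],
                            sample(values, size, replace = FALSE))
    if (length(unique(sub)) < 2L) {
      warn(sprintf("Subsample %d has < 2 distinct values; skipped.", i))
      n_skipped <- n_skipped + 1L
      next
    }
    th <- kmeans_threshold(sub, seed = seeds[n_subsamples + i],
                           n_init = n_init)$threshold
    rows[[i]] <- tibble(subsample = i, n = size, threshold = th)
  }
  thresholds <- dplyr::bind_rows(rows)
  list(
    thresholds = thresholds,
    summary = tibble(mean = mean(thresholds$threshold),
                     sd = sd(thresholds$threshold),
                     min = min(thresholds$threshold),
                     max = max(thresholds$threshold),
                     n_skipped = n_skipped))
}
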