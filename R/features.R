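#' Pain volatility of a severity series
#'
#' Pain volatility is the mean of absolute changes between consecutive pain
#' severity ratings within an observation window:
#' `sum(|r[i] - r[i-1]|) / (n - 1)` over a time-ordered series of `n`
#' ratings. It is translation-invariant and scales linearly with the rating
#' scale.
#'
#' @param ratings Numeric vector of severity ratings, already in time order.
#' @return A single non-negative number.
#' @examples
#' compute_volatility(c(3, 3, 3, 3))   # 0
#' compute_volatility(c(2, 5, 3))      # 2.5
#' compute_volatility(c(0, 10, 0, 10)) # 10
#' @export
compute_volatility <- function(ratings) {
  if (!is.numeric(ratings) || anyNA(ratings)) {
    abort("`ratings` must be a numeric vector without missing values.",
          class = "painvol_validation_error")
  }
  if (length(ratings) < 2L) {
    abort("Pain volatility is undefined for fewer than 2 ratings.",
          class = "painvol_undefined_volatility")
  }
  mean(abs(diff(ratings)))
}

#' Trend-line change over an observation window
#'
#' Fits an ordinary least-squares line through `(time, rating)` points and
#' returns the fitted change from the first to the last observation time
#' (`delta = slope * (t_n - t_1)`) together with its absolute value. These
#' are two of the pain-statistics features: a signed summary of whether pain
#' drifted up or down over the window, and its magnitude.
#'
#' @param times Numeric or Date vector of observation times.
#' @param ratings Numeric vector of severity ratings, same length.
#' @return A named list with elements `delta` and `abs_delta`.
#' @examples
#' trend_delta(1:5, 1:5)          # delta 4
#' trend_delta(c(0, 10), c(5, 1)) # delta -4
#' @export
trend_delta <- function(times, ratings) {
  times <- as.numeric(times)
  if (length(times) != length(ratings) || length(times) < 2L) {
    abort("`times` and `ratings` must be equal-length vectors of length >= 2.",
          class = "painvol_validation_error")
  }
  if (anyNA(times) || anyNA(ratings)) {
    abort("`times` and `ratings` must not contain missing values.",
          class = "painvol_validation_error")
  }
  tc <- times - mean(times)
  sxx <- sum(tc^2)
  if (sxx == 0) {
    abort("Trend line is undefined when all observation times coincide.",
          class = "painvol_degenerate_fit")
  }
  slope <- sum(tc * (ratings - mean(ratings))) / sxx
  delta <- slope * (times[length(times)] - times[1L])
  list(delta = delta, abs_delta = abs(delta))
}

#' Assign records to the predictor and outcome windows
#'
#' The predictor window covers days 0-29 from each user's first record; the
#' outcome window covers days 150-179 (the sixth 30-day block). Records
#' outside both windows get `NA`.
#'
#' @param records A records tibble with `user_id` and `date` columns.
#' @return `records` with an added `window` column
#'   (`"predictor"` / `"outcome"` / `NA`) and a `day` offset column.
#' @export
assign_windows <- function(records) {
  if (!all(c("user_id", "date") %in% names(records))) {
    abort("`records` must have `user_id` and `date` columns.",
          class = "painvol_validation_error")
  }
  records |>
    group_by(.data$user_id) |>
    mutate(day = as.integer(as.numeric(.data$date - min(.data$date)))) |>
    ungroup() |>
    mutate(window = dplyr::case_when(
      .data$day >= 0L & .data$day <= 29L ~ "predictor",
      .data$day >= 150L & .data$day <= 179L ~ "outcome",
      TRUE ~ NA_character_
    ))
}

# Volatility statistics for one ordered severity series; NA-safe variant
# used internally (callers guarantee eligibility where it matters).
vol_stat <- function(x) if (length(x) < 2L) NA_real_ else mean(abs(diff(x)))
vol_sd_stat <- function(x) {
  if (length(x) < 3L) 0 else sd(abs(diff(x)))
}

#' Per-user, per-window volatility values
#'
#' Computes the pain volatility statistic for every (user, window) pair with
#' at least 2 records. Records are ordered by date within user and window;
#' same-day records keep their input order.
#'
#' @param records A records tibble (`user_id`, `date`, `severity`); a
#'   `window` column is added via [assign_windows()] when absent.
#' @return A tibble `user_id`, `window`, `n_records`, `volatility`.
#' @export
window_volatility <- function(records) {
  if (!"window" %in% names(records)) records <- assign_windows(records)
  records |>
    filter(!is.na(.data$window)) |>
    group_by(.data$user_id, .data$window) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(n_records = dplyr::n(),
              volatility = vol_stat(.data$severity),
              .groups = "drop")
}

#' Inclusion filter: enough records in both windows
#'
#' Retains users with at least `min_records` pain records in the predictor
#' window and at least `min_records` in the outcome window. Users failing
#' either bound are excluded.
#'
#' @param records A records tibble; window assignment is added when absent.
#' @param min_records Minimum records required per window (default 5).
#' @return A tibble of eligible users: `user_id`, `n_predictor`,
#'   `n_outcome`.
#' @export
filter_users <- function(records, min_records = 5L) {
  min_records <- assert_count(min_records, "min_records")
  if (!"window" %in% names(records)) records <- assign_windows(records)
  records |>
    filter(!is.na(.data$window)) |>
    dplyr::count(.data$user_id, .data$window) |>
    tidyr::pivot_wider(names_from = "window", values_from = "n",
                       values_fill = 0L,
                       names_prefix = "n_") |>
    (\(w) {
      for (col in c("n_predictor", "n_outcome"))
        if (!col %in% names(w)) w[[col]] <- 0L
      w
    })() |>
    filter(.data$n_predictor >= min_records,
           .data$n_outcome >= min_records) |>
    select("user_id", "n_predictor", "n_outcome") |>
    arrange(.data$user_id)
}

# Encode gender on one numeric slot: male 0, female 1, missing/other 0.5.
encode_gender <- function(g) {
  dplyr::case_when(g %in% "female" ~ 1, g %in% "male" ~ 0, TRUE ~ 0.5)
}

# Long (user_id, feature) presence pairs from ';'-joined token columns.
# Tokens absent from the vocabulary are dropped with a warning.
presence_pairs <- function(tbl, fields, id) {
  out <- vector("list", length(fields))
  for (j in seq_along(fields)) {
    field <- fields[[j]]
    if (!field %in% names(tbl)) next
    toks <- strsplit(dplyr::coalesce(tbl[[field]], ""), ";", fixed = TRUE)
    lens <- lengths(toks)
    long <- tibble(user_id = rep(tbl[[id]], lens),
                   token = unlist(toks, use.names = FALSE))
    long <- long[long$token != "", , drop = FALSE]
    unknown <- setdiff(unique(long$token), pv_vocab[[field]])
    if (length(unknown) > 0L) {
      warn(sprintf("Dropping %d unknown token(s) in field '%s': %s",
                   length(unknown), field,
                   paste(head(unknown, 5L), collapse = ", ")))
      long <- long[long$token %in% pv_vocab[[field]], , drop = FALSE]
    }
    long$feature <- pv_feature_name(field, long$token)
    out[[j]] <- distinct(long[c("user_id", "feature")])
  }
  dplyr::bind_rows(out)
}

#' Extract the 132-feature representation of each user
#'
#' Builds one feature vector per eligible user from the records of a single
#' observation window, following the fixed [feature_schema()]: demographics
#' (encoded gender; age, median-imputed over the extracted users when
#' missing), app usage (record count and distinct-day count in the window),
#' eight pain statistics (mean/SD of severity, mean/SD of absolute
#' consecutive changes, trend-line delta and its absolute value, and two
#' binary level features), and binary presence indicators for every
#' descriptor, factor, condition, medication and mental-health token.
#'
#' The two level features dichotomize the window's mean severity and its
#' volatility at the supplied thresholds (`>=` threshold codes 1).
#'
#' @param records Records tibble; window assignment added when absent.
#' @param profiles Profiles tibble (`user_id`, `age`, `gender`,
#'   `conditions`, `medications`, `mental_health`).
#' @param users Character vector of users to extract (typically
#'   `filter_users(records)$user_id`). Defaults to all users present in the
#'   chosen window.
#' @param window `"predictor"` (default) or `"outcome"`.
#' @param volatility_threshold,severity_threshold Numeric cut points for the
#'   two binary level features (see [kmeans_threshold()]).
#' @param schema Feature schema; defaults to [feature_schema()].
#' @return A tibble with `user_id` followed by 132 numeric feature columns
#'   in schema order. No missing values remain after imputation.
#' @export
extract_features <- function(records, profiles, users = NULL,
                             window = c("predictor", "outcome"),
                             volatility_threshold = 1.6,
                             severity_threshold = 5,
                             schema = feature_schema()) {
  window <- match.arg(window)
  assert_scalar_number(volatility_threshold, "volatility_threshold")
  assert_scalar_number(severity_threshold, "severity_threshold")
  if (!"window" %in% names(records)) records <- assign_windows(records)
  rec <- filter(records, .data$window == !!window)
  if (is.null(users)) users <- sort(unique(rec$user_id))
  missing_profiles <- setdiff(users, profiles$user_id)
  if (length(missing_profiles) > 0L) {
    abort(sprintf("No profile for user(s): %s",
                  paste(head(missing_profiles, 5L), collapse = ", ")),
          class = "painvol_validation_error")
  }
  rec <- filter(rec, .data$user_id %in% users)

  stats <- rec |>
    group_by(.data$user_id) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(
      n_records = dplyr::n(),
      n_days = dplyr::n_distinct(.data$date),
      severity_mean = mean(.data$severity),
      severity_sd = if (dplyr::n() < 2L) 0 else sd(.data$severity),
      abs_change_mean = if (dplyr::n() < 2L) 0
                        else mean(abs(diff(.data$severity))),
      abs_change_sd = vol_sd_stat(.data$severity),
      trend_delta = if (dplyr::n_distinct(.data$date) < 2L) 0
                    else trend_delta(.data$date, .data$severity)$delta,
      .groups = "drop") |>
    mutate(trend_abs_delta = abs(.data$trend_delta),
           severity_level = as.numeric(.data$severity_mean >=
                                         severity_threshold),
           volatility_level = as.numeric(.data$abs_change_mean >=
                                           volatility_threshold))

  prof <- profiles |>
    filter(.data$user_id %in% users) |>
    mutate(gender = encode_gender(.data$gender),
           age = {
             a <- as.numeric(.data$age)
             if (anyNA(a)) a[is.na(a)] <- median(a, na.rm = TRUE)
             a
           }) |>
    select("user_id", "gender", "age")

  presence <- dplyr::bind_rows(
    presence_pairs(rec, pv_record_fields, "user_id"),
    presence_pairs(filter(profiles, .data$user_id %in% users),
                   pv_profile_fields, "user_id"))

  out <- tibble(user_id = users) |>
    left_join(prof, by = "user_id") |>
    left_join(stats, by = "user_id")

  binary_features <- schema$feature[schema$subcategory %in%
                                      c(pv_record_fields, pv_profile_fields)]
  pres_mat <- matrix(0, nrow = length(users), ncol = length(binary_features),
                     dimnames = list(NULL, binary_features))
  if (nrow(presence) > 0L) {
    presence <- filter(presence, .data$feature %in% binary_features)
    pres_mat[cbind(match(presence$user_id, users),
                   match(presence$feature, binary_features))] <- 1
  }
  out <- dplyr::bind_cols(out, as_tibble(pres_mat))

  absent <- setdiff(schema$feature, names(out))
  if (length(absent) > 0L) {
    abort(paste0("Internal schema mismatch; missing feature(s): ",
                 paste(head(absent, 5L), collapse = ", ")),
          class = "painvol_internal_error")
  }
  out <- out[, c("user_id", schema$feature)]
  if (anyNA(out)) {
    abort("Feature extraction produced missing values.",
          class = "painvol_internal_error")
  }
  out
}
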