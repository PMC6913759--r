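#' Simulation parameters for a synthetic diary cohort
#'
#' Builds a validated parameter set for [simulate_cohort()]. The defaults
#' describe the population the package targets: a few hundred app users, a
#' roughly 4:1 split between low- and high-volatility users, severity
#' recorded on a continuous 0-10 visual-analogue scale, and about a dozen
#' records in each 30-day observation window.
#'
#' Each user's severity series is a reflected Gaussian random walk on
#' \[0, 10\]. The per-step standard deviation is `step_scale * sqrt(pi / 2)`,
#' which makes the expected mean absolute consecutive change — the pain
#' volatility statistic — equal to the class's `step_scale` (before boundary
#' reflection, which dampens large steps slightly).
#'
#' @param n_users Number of users to simulate.
#' @param prop_high Fraction of users planted as high-volatility in the
#'   predictor window; must be strictly inside (0, 1).
#' @param base_severity_mean,base_severity_sd Mean and SD of the walk's
#'   starting severity, on the 0-10 scale.
#' @param step_scale_low,step_scale_high Target mean absolute consecutive
#'   severity change for the low and the high class. `step_scale_high` must
#'   exceed `step_scale_low`; `step_scale_low = 0` yields constant series.
#' @param class_persistence Probability that a user's outcome-window class
#'   equals their predictor-window class.
#' @param records_per_window_mean Mean of the Poisson record count per
#'   30-day window. Counts are floored at `min_records` and capped at 30
#'   (record days are drawn without replacement within the window).
#' @param min_records Floor on the per-window record count.
#' @param n_informative_descriptors Number of record-level descriptor tokens
#'   whose per-record occurrence probability differs between classes.
#' @param descriptor_effect Occurrence-probability shift for informative
#'   descriptors in high-volatility windows.
#' @param descriptor_base_rate Per-record occurrence probability of every
#'   non-informative descriptor token.
#' @param seed Integer seed; identical parameters (including the seed)
#'   reproduce the cohort exactly.
#' @return A `pv_sim_params` list.
#' @examples
#' sim_params(n_users = 50, seed = 1)
#' @export
sim_params <- function(n_users = 879,
                       prop_high = 0.21,
                       base_severity_mean = 5,
                       base_severity_sd = 1.5,
                       step_scale_low = 0.8,
                       step_scale_high = 2.5,
                       class_persistence = 0.8,
                       records_per_window_mean = 12,
                       min_records = 2,
                       n_informative_descriptors = 2,
                       descriptor_effect = 0.1,
                       descriptor_base_rate = 0.04,
                       seed = 1) {
  n_users <- assert_count(n_users, "n_users")
  assert_scalar_number(prop_high, "prop_high")
  if (prop_high <= 0 || prop_high >= 1) {
    abort("`prop_high` must lie strictly inside (0, 1).",
          class = "painvol_config_error")
  }
  assert_scalar_number(base_severity_mean, "base_severity_mean", 0, 10)
  assert_scalar_number(base_severity_sd, "base_severity_sd", 0)
  assert_scalar_number(step_scale_low, "step_scale_low", 0)
  assert_scalar_number(step_scale_high, "step_scale_high", 0)
  if (step_scale_high <= step_scale_low) {
    abort("`step_scale_high` must exceed `step_scale_low`.",
          class = "painvol_config_error")
  }
  assert_scalar_number(class_persistence, "class_persistence", 0, 1)
  assert_scalar_number(records_per_window_mean, "records_per_window_mean", 0)
  if (records_per_window_mean <= 0) {
    abort("`records_per_window_mean` must be positive.",
          class = "painvol_config_error")
  }
  min_records <- assert_count(min_records, "min_records", min = 2L)
  n_informative_descriptors <-
    assert_count(n_informative_descriptors, "n_informative_descriptors",
                 min = 0L)
  n_record_tokens <- sum(lengths(pv_vocab[pv_record_fields]))
  if (n_informative_descriptors > n_record_tokens) {
    abort(sprintf(
      "`n_informative_descriptors` cannot exceed the %d record-level tokens.",
      n_record_tokens), class = "painvol_config_error")
  }
  assert_scalar_number(descriptor_effect, "descriptor_effect", 0, 1)
  assert_scalar_number(descriptor_base_rate, "descriptor_base_rate", 0, 1)
  if (descriptor_base_rate + descriptor_effect > 1) {
    abort("`descriptor_base_rate + descriptor_effect` must not exceed 1.",
          class = "painvol_config_error")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(n_users = n_users, prop_high = prop_high,
         base_severity_mean = base_severity_mean,
         base_severity_sd = base_severity_sd,
         step_scale_low = step_scale_low, step_scale_high = step_scale_high,
         class_persistence = class_persistence,
         records_per_window_mean = records_per_window_mean,
         min_records = min_records,
         n_informative_descriptors = n_informative_descriptors,
         descriptor_effect = descriptor_effect,
         descriptor_base_rate = descriptor_base_rate,
         seed = seed),
    class = "pv_sim_params"
  )
}

# Fold a free walk into [0, 10]: a reflected random walk equals the free
# (unbounded) walk folded at the boundaries.
fold_0_10 <- function(x) {
  y <- x %% 20
  ifelse(y > 10, 20 - y, y)
}

# ";"-join present tokens per row of a logical matrix, preserving vocabulary
# order. Rows with no token become "".
join_tokens <- function(present, tokens) {
  out <- character(nrow(present))
  idx <- which(present, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    per_row <- split(tokens[idx[, 2L]], idx[, 1L])
    out[as.integer(names(per_row))] <-
      vapply(per_row, paste, character(1), collapse = ";")
  }
  out
}

#' Simulate a synthetic pain-diary cohort
#'
#' Generates per-user pain records for two 30-day observation windows — the
#' predictor window (days 0-29 from the user's first record) and the outcome
#' window (days 150-179, the sixth month) — together with static user
#' profiles and the planted per-window volatility classes.
#'
#' Severity follows a reflected Gaussian random walk whose step scale is set
#' by the user's planted class in that window; the outcome-window class
#' repeats the predictor-window class with probability `class_persistence`.
#' A configurable number of record-level descriptor tokens are informative:
#' their occurrence probability is raised by `descriptor_effect` in
#' high-volatility windows. All other descriptor, condition, medication and
#' mental-health tokens occur at class-independent base rates.
#'
#' @param params A [sim_params()] object (or missing for the defaults).
#' @return A `pv_cohort` list with tibbles `profiles` (one row per user:
#'   `user_id`, `age`, `gender`, plus `;`-joined `conditions`,
#'   `medications`, `mental_health`), `records` (one row per record:
#'   `user_id`, `date`, `severity`, plus one `;`-joined column per
#'   record-level descriptor field), and `truth` (planted classes
#'   `class_predictor`, `class_outcome` per user), plus the `params` used.
#' @examples
#' cohort <- simulate_cohort(sim_params(n_users = 20, seed = 7))
#' cohort$records
#' cohort$truth
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "pv_sim_params")) {
    abort("`params` must come from sim_params().",
          class = "painvol_config_error")
  }
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  n <- params$n_users
  user_id <- sprintf("u%05d", seq_len(n))

  class_pred <- ifelse(runif(n) < params$prop_high, "high", "low")
  keep <- runif(n) < params$class_persistence
  class_out <- ifelse(keep, class_pred,
                      ifelse(class_pred == "high", "low", "high"))

  truth <- tibble(user_id = user_id,
                  class_predictor = class_pred,
                  class_outcome = class_out)

  profiles <- tibble(
    user_id = user_id,
    age = {
      a <- as.integer(pmin(pmax(round(rnorm(n, 48, 14)), 18L), 90L))
      a[runif(n) < 0.05] <- NA_integer_
      a
    },
    gender = {
      g <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(0.46, 0.54))
      g[runif(n) < 0.02] <- NA_character_
      g
    },
    conditions = join_tokens(
      matrix(runif(n * 6) < 0.20, n), pv_vocab$conditions),
    medications = join_tokens(
      matrix(runif(n * 5) < 0.25, n), pv_vocab$medications),
    mental_health = join_tokens(
      matrix(runif(n * 2) < 0.15, n), pv_vocab$mental_health)
  )

  first_date <- as.Date("2023-01-01") + sample.int(365L, n, replace = TRUE) - 1L

  window_offsets <- c(predictor = 0L, outcome = 150L)
  window_class <- cbind(predictor = class_pred, outcome = class_out)

  rec_list <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (w in names(window_offsets)) {
      n_rec <- min(30L, max(params$min_records,
                            rpois(1L, params$records_per_window_mean)))
      # the predictor window is anchored at the user's first record, so
      # day 0 always carries one
      days <- if (w == "predictor") {
        c(0L, sort(sample.int(29L, n_rec - 1L)))
      } else {
        sort(sample.int(30L, n_rec)) - 1L
      }
      scale <- if (window_class[i, w] == "high") params$step_scale_high
               else params$step_scale_low
      start <- fold_0_10(rnorm(1L, params$base_severity_mean,
                               params$base_severity_sd))
      steps <- rnorm(n_rec - 1L, 0, scale * sqrt(pi / 2))
      severity <- fold_0_10(start + c(0, cumsum(steps)))
      k <- k + 1L
      rec_list[[k]] <- tibble(
        user_id = user_id[i],
        date = first_date[i] + window_offsets[[w]] + days,
        severity = severity,
        .high = window_class[i, w] == "high"
      )
    }
  }
  records <- dplyr::bind_rows(rec_list)

  # Descriptor occurrence: informative tokens (the first
  # n_informative_descriptors across the record-level fields, in schema
  # order) get their rate shifted upward in high-volatility windows.
  n_inf_left <- params$n_informative_descriptors
  m <- nrow(records)
  for (field in pv_record_fields) {
    tokens <- pv_vocab[[field]]
    p <- matrix(params$descriptor_base_rate, m, length(tokens))
    n_inf_here <- min(n_inf_left, length(tokens))
    if (n_inf_here > 0L) {
      p[records$.high, seq_len(n_inf_here)] <-
        params$descriptor_base_rate + params$descriptor_effect
      n_inf_left <- n_inf_left - n_inf_here
    }
    present <- matrix(runif(m * length(tokens)), m) < p
    records[[field]] <- join_tokens(present, tokens)
  }
  records$.high <- NULL

  structure(list(profiles = profiles, records = records, truth = truth,
                 params = params),
            class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf(
    "<pv_cohort> %d users, %d pain records (seed %d)\n",
    nrow(x$profiles), nrow(x$records), x$params$seed))
  cat(sprintf("  planted high-volatility (predictor window): %d\n",
              sum(x$truth$class_predictor == "high")))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' A cohort is stored as two UTF-8 CSV files with header rows,
#' `profiles.csv` and `records.csv`, in the directory `path`. Set-valued
#' fields (descriptors, conditions, medications) are serialized as
#' `;`-joined tokens; an empty set is an empty string; missing age or gender
#' is written as `NA`. Column order is fixed as produced by
#' [simulate_cohort()].
#'
#' @param cohort A `pv_cohort`, or any list with `profiles` and `records`
#'   tibbles in the documented layout.
#' @param path Directory to write to (created if needed).
#' @return `write_cohort()` returns the two file paths invisibly;
#'   `read_cohort()` returns a `pv_cohort` (without planted truth).
#' @examples
#' dir <- tempfile()
#' cohort <- simulate_cohort(sim_params(n_users = 10, seed = 3))
#' write_cohort(cohort, dir)
#' back <- read_cohort(dir)
#' all.equal(back$records$severity, cohort$records$severity)
#' @export
write_cohort <- function(cohort, path) {
  if (is.null(cohort$profiles) || is.null(cohort$records)) {
    abort("`cohort` must contain `profiles` and `records` tables.",
          class = "painvol_validation_error")
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- c(profiles = file.path(path, "profiles.csv"),
             records = file.path(path, "records.csv"))
  readr::write_csv(cohort$profiles, files[["profiles"]], na = "NA")
  readr::write_csv(cohort$records, files[["records"]], na = "NA")
  invisible(files)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  files <- c(profiles = file.path(path, "profiles.csv"),
             records = file.path(path, "records.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    abort(paste0("Cohort file(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "painvol_io_error")
  }
  profiles <- readr::read_csv(
    files[["profiles"]], na = "NA", show_col_types = FALSE,
    col_types = readr::cols(
      user_id = readr::col_character(),
      age = readr::col_integer(),
      gender = readr::col_character(),
      .default = readr::col_character()))
  records <- readr::read_csv(
    files[["records"]], na = "NA", show_col_types = FALSE,
    col_types = readr::cols(
      user_id = readr::col_character(),
      date = readr::col_date(),
      severity = readr::col_double(),
      .default = readr::col_character()))
  validate_records(records)
  descriptor_cols <- setdiff(names(records), c("user_id", "date", "severity"))
  records[descriptor_cols] <-
    lapply(records[descriptor_cols], function(x) dplyr::coalesce(x, ""))
  structure(list(profiles = profiles, records = records, truth = NULL,
                 params = NULL),
            class = "pv_cohort")
}

# Row-level validation shared by read_cohort() and callers ingesting
# external tables. Line numbers reported are 1-based data rows (header
# excluded).
validate_records <- function(records) {
  required <- c("user_id", "date", "severity")
  absent <- setdiff(required, names(records))
  if (length(absent) > 0L) {
    abort(paste0("records table lacks required column(s): ",
                 paste(absent, collapse = ", ")),
          class = "painvol_parse_error")
  }
  bad <- which(is.na(records$user_id) | is.na(records$date) |
                 is.na(records$severity))
  if (length(bad) > 0L) {
    abort(sprintf(
      "records row %d: missing user_id, date or severity.", bad[1L]),
      class = "painvol_parse_error")
  }
  oob <- which(records$severity < 0 | records$severity > 10)
  if (length(oob) > 0L) {
    abort(sprintf(
      "records row %d: severity %.3f outside [0, 10].",
      oob[1L], records$severity[oob[1L]]),
      class = "painvol_validation_error")
  }
  invisible(records)
}
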