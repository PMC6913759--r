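# In-code fixtures: small record/profile tables with known structure.

# One user's records on given day offsets from `start`.
make_records <- function(user_id, days, severity,
                         start = as.Date("2023-06-01"), ...) {
  tibble::tibble(user_id = user_id, date = start + days,
                 severity = severity, ...)
}

# A minimal profile row compatible with extract_features().
make_profile <- function(user_id, age = 40L, gender = "female",
                         conditions = "", medications = "",
                         mental_health = "") {
  tibble::tibble(user_id = user_id, age = age, gender = gender,
                 conditions = conditions, medications = medications,
                 mental_health = mental_health)
}

# A small simulated cohort shared by several tests (memoised per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_params(n_users = 150, seed = 421))
    }
    cache
  }
})
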