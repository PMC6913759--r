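#' Per-class and overall accuracy
#'
#' Summarises predictions against reference labels as a three-row confusion
#' summary: accuracy on the low-volatility class (specificity, treating low
#' volatility as the control group), accuracy on the high-volatility class
#' (sensitivity), and overall accuracy.
#'
#' @param predictions Predicted classes (`"low"`/`"high"`).
#' @param labels Reference classes, same length.
#' @return A tibble `class` (`"low"`, `"high"`, `"overall"`), `n`,
#'   `correct`, `accuracy`.
#' @examples
#' score(rep(c("low", "high"), c(8, 2)), rep(c("low", "high"), c(7, 3)))
#' @export
score <- function(predictions, labels) {
  pred <- class_factor(predictions)
  ref <- class_factor(labels)
  if (length(pred) != length(ref)) {
    abort("`predictions` and `labels` must have the same length.",
          class = "painvol_validation_error")
  }
  if (anyNA(pred) || anyNA(ref)) {
    abort("Classes must be \"low\" or \"high\".",
          class = "painvol_validation_error")
  }
  per_class <- tibble(class = c("low", "high")) |>
    mutate(n = vapply(.data$class, function(cl) sum(ref == cl), integer(1),
                      USE.NAMES = FALSE),
           correct = vapply(.data$class,
                            function(cl) sum(ref == cl & pred == cl),
                            integer(1), USE.NAMES = FALSE))
  dplyr::bind_rows(
    per_class,
    tibble(class = "overall", n = length(ref),
           correct = sum(pred == ref))) |>
    mutate(accuracy = ifelse(.data$n > 0, .data$correct / .data$n, NA_real_))
}

#' Consolidate per-subsample predictions by majority vote
#'
#' A user is assigned to the high-volatility class when at least
#' `ceil(S / 2 + 0.5)` of the `S` per-subsample models predict high — at
#' least 3 of 5 with the default grid. `S` must be odd, so ties cannot
#' occur.
#'
#' @param votes A matrix or tibble of predicted classes, one row per user
#'   and one column per subsample model.
#' @return A factor of consolidated classes, one per row.
#' @examples
#' majority_vote(rbind(c("high", "high", "high", "low", "low"),
#'                     c("high", "high", "low", "low", "low")))
#' @export
majority_vote <- function(votes) {
  votes <- as.matrix(votes)
  if (anyNA(votes)) {
    abort("Missing votes: every user needs one prediction per subsample.",
          class = "painvol_validation_error")
  }
  if (ncol(votes) %% 2L == 0L) {
    abort("The number of subsample votes must be odd.",
          class = "painvol_validation_error")
  }
  if (!all(votes %in% c("low", "high"))) {
    abort("Votes must be \"low\" or \"high\".",
          class = "painvol_validation_error")
  }
  need <- ceiling(ncol(votes) / 2 + 0.5)
  class_factor(ifelse(rowSums(votes == "high") >= need, "high", "low"))
}
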