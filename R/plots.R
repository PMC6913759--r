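#' Plot a volatility labeling
#'
#' Scatter of volatility values by index (predictor-window points first,
#' then outcome-window points when assignments are present), colored by
#' class, with a horizontal line at the class threshold.
#'
#' @param object A `pv_labeling` from [kmeans_threshold()] or
#'   [label_volatility()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_labeling <- function(object, ...) {
  d <- tidy(object)
  if ("window" %in% names(d)) {
    d <- arrange(d, dplyr::desc(.data$window), .data$user_id)  # predictor first
    d$value <- d$volatility
  }
  d$index <- seq_len(nrow(d))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$value,
                                       colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "solid") +
    ggplot2::scale_colour_manual(values = c(low = "black", high = "red")) +
    ggplot2::labs(x = "data point index", y = "pain volatility",
                  colour = "class",
                  subtitle = sprintf("threshold = %.2f", object$threshold)) +
    ggplot2::theme_minimal()
  if ("window" %in% names(d)) {
    p <- p + ggplot2::geom_vline(xintercept = sum(d$window == "predictor") +
                                   0.5, linetype = "dotted")
  }
  p
}

#' Plot per-training-set importance rankings
#'
#' Importance score against rank for each training set, one panel per
#' ranking method — the view used to judge where scores stop decreasing
#' when choosing top-set sizes.
#'
#' @param object A `pv_consensus` from [consensus_select()].
#' @param top_n Ranks shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_consensus <- function(object, top_n = 20L, ...) {
  d <- filter(object$rankings, .data$rank <= top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$importance,
                                  group = .data$set_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "feature rank within training set",
                  y = "importance score") +
    ggplot2::theme_minimal()
}

#' Plot experiment accuracies
#'
#' Per-subsample and consolidated accuracies by model family, faceted by
#' class and feature set.
#'
#' @param object A `pv_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_experiment <- function(object, ...) {
  d <- mutate(object$results,
              subsample = factor(.data$subsample,
                                 levels = c(sort(unique(setdiff(
                                   .data$subsample, "consolidated"))),
                                   "consolidated")),
              class = factor(.data$class,
                             levels = c("low", "high", "overall")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subsample, y = .data$accuracy,
                                  fill = .data$family)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(class ~ feature_set) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = NULL, y = "accuracy", fill = "model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  }
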