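new_pv_model <- function(family, fit, features, seed, extra = list()) {
  structure(c(list(family = family, fit = fit, features = features,
                   seed = seed), extra),
            class = "pv_model")
}

#' @export
print.pv_model <- function(x, ...) {
  cat(sprintf("<pv_model> family %s; %d features; seed %d\n",
              x$family, length(x$features), x$seed))
  invisible(x)
}

#' Train a random forest volatility classifier
#'
#' Fits a bootstrap random forest with Gini splitting, `n_trees` trees and
#' `mtry` candidate features per node (default `floor(sqrt(p))`). The fit
#' keeps its in-bag bootstrap counts and full tree structure so that
#' [gini_importance()] can recompute node-level impurity statistics from it.
#'
#' @param data Feature table (tibble/data frame/matrix; feature columns
#'   only).
#' @param labels Class labels (`"low"` / `"high"`).
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed; identical seed and inputs give identical fits.
#' @return A `pv_model` of family `"rf"`.
#' @export
train_rf <- function(data, labels, n_trees = 100L, mtry = NULL, seed = 1L) {
  n_trees <- assert_count(n_trees, "n_trees")
  x <- as.data.frame(data)
  y <- class_factor(labels)
  if (anyNA(y)) {
    abort("`labels` must be \"low\"/\"high\".",
          class = "painvol_validation_error")
  }
  mtry <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(x))))
          else assert_count(mtry, "mtry")
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                               keep.forest = TRUE, keep.inbag = TRUE))
  new_pv_model("rf", fit, colnames(x), seed,
               list(n_trees = n_trees, mtry = mtry))
}

#' Train a penalized logistic-regression volatility classifier
#'
#' Fits an L2- (ridge) or L1- (LASSO) penalized logistic regression with the
#' penalty strength chosen by internal cross-validation on the training set
#' only; predictors are standardized internally. Classification uses a 0.5
#' probability threshold, appropriate for the balanced training sets the
#' pipeline produces.
#'
#' @inheritParams train_rf
#' @param penalty `"ridge"` or `"lasso"`.
#' @param lambda Optional numeric penalty grid; defaults to the fitted
#'   path's own grid.
#' @param cv_folds Folds of the internal cross-validation (default 5).
#' @return A `pv_model` of family `"logreg_ridge"` or `"logreg_lasso"`.
#' @export
train_logreg <- function(data, labels, penalty = c("ridge", "lasso"),
                         lambda = NULL, cv_folds = 5L, seed = 1L) {
  penalty <- match.arg(penalty)
  cv_folds <- assert_count(cv_folds, "cv_folds", min = 3L)
  x <- as.matrix(as.data.frame(data))
  y <- class_factor(labels)
  if (anyNA(y)) {
    abort("`labels` must be \"low\"/\"high\".",
          class = "painvol_validation_error")
  }
  if (all(apply(x, 2L, function(col) length(unique(col)) == 1L))) {
    abort("Design is degenerate: every feature is constant.",
          class = "painvol_validation_error")
  }
  fit <- withr::with_seed(seed,
    glmnet::cv.glmnet(x, y, family = "binomial",
                      alpha = if (penalty == "ridge") 0 else 1,
                      lambda = lambda, nfolds = cv_folds,
                      standardize = TRUE))
  new_pv_model(paste0("logreg_", penalty), fit, colnames(x), seed,
               list(penalty = penalty, lambda = fit$lambda.min))
}

#' Predict volatility classes
#'
#' Deterministic given the model: the predicted probability of the high
#' class is the fraction of trees voting high (random forest) or the fitted
#' logistic probability at the cross-validated penalty (logistic
#' regression); the class is `"high"` iff that probability is at least 0.5.
#'
#' @param object A `pv_model`.
#' @param new_data Feature table containing at least the model's features
#'   (extra columns, e.g. `user_id`, are ignored).
#' @param ... Unused.
#' @return A tibble with `.pred_class` (factor low/high) and `.pred_high`
#'   (probability of the high class). Zero rows in, zero rows out.
#' @export
predict.pv_model <- function(object, new_data, ...) {
  new_data <- as.data.frame(new_data)
  missing_f <- setdiff(object$features, colnames(new_data))
  if (length(missing_f) > 0L) {
    abort(paste0("new_data lacks feature(s): ",
                 paste(head(missing_f, 5L), collapse = ", ")),
          class = "painvol_schema_error")
  }
  x <- new_data[, object$features, drop = FALSE]
  if (nrow(x) == 0L) {
    return(tibble(.pred_class = class_factor(character()),
                  .pred_high = numeric()))
  }
  p_high <- switch(
    object$family,
    rf = unname(predict(object$fit, x, type = "vote",
                        norm.votes = TRUE)[, "high"]),
    logreg_ridge = ,
    logreg_lasso = as.numeric(predict(object$fit, as.matrix(x),
                                      s = "lambda.min",
                                      type = "response")),
    abort(paste0("Unknown model family: ", object$family)))
  tibble(.pred_class = class_factor(ifelse(p_high >= 0.5, "high", "low")),
         .pred_high = p_high)
}
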