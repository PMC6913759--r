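entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Equal-frequency discretization
#'
#' Bins a numeric feature at its empirical quantiles. Features with at most
#' two distinct values (binary indicators) are returned as-is; ties in the
#' quantiles collapse bins, so heavily tied features get fewer bins.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (default 10).
#' @return A factor.
#' @export
discretize_ef <- function(x, bins = 10L) {
  bins <- assert_count(bins, "bins", min = 2L)
  ux <- unique(x)
  if (length(ux) <= 2L) return(factor(x))
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                            names = FALSE, type = 7))
  if (length(breaks) < 3L) return(factor(x))
  cut(x, breaks = breaks, include.lowest = TRUE)
}

#' Information gain of a feature about a binary outcome
#'
#' `IG = H(Y) - H(Y | X)` in bits, where continuous features are first
#' discretized (equal-frequency, `bins` bins) and `H(Y | X)` is the
#' bin-weighted entropy of the outcome. IG lies in `[0, H(Y)]`; for a
#' balanced binary outcome a feature identical to the label scores exactly
#' 1 bit.
#'
#' @param x Feature values (numeric, factor or character).
#' @param y Binary outcome labels.
#' @param discretizer Function mapping a numeric vector to a factor;
#'   defaults to [discretize_ef()] with `bins` bins.
#' @param bins Bin count for the default discretizer.
#' @return A single non-negative number (bits).
#' @examples
#' y <- rep(c("low", "high"), each = 4)
#' information_gain(as.numeric(y == "high"), y)  # 1 bit
#' @export
information_gain <- function(x, y, discretizer = NULL, bins = 10L) {
  y <- factor(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "painvol_validation_error")
  }
  if (nlevels(droplevels(y)) < 2L) {
    warn("Outcome has a single class; information gain is 0 by convention.")
    return(0)
  }
  if (is.numeric(x)) {
    x <- if (is.null(discretizer)) discretize_ef(x, bins) else discretizer(x)
  }
  x <- factor(x)
  h_y <- entropy_bits(table(y))
  tab <- table(x, y)
  w <- rowSums(tab) / sum(tab)
  h_cond <- sum(w * apply(tab, 1L, entropy_bits))
  max(0, h_y - h_cond)
}

#' Mean-decrease-impurity (Gini) feature importance
#'
#' Recomputes the Gini importance of every feature from a trained random
#' forest's node statistics: the training samples are routed down each tree
#' using the stored splits and per-tree bootstrap (in-bag) weights, and each
#' split on a feature contributes
#' `(n_parent / n_total) * (G_parent - (n_L / n_parent) G_L -
#' (n_R / n_parent) G_R)`, where `G` is the Gini impurity of the weighted
#' class counts reaching a node. Per-feature contributions are summed over
#' splits and averaged over trees; scores are non-negative and a feature
#' never used in a split scores 0.
#'
#' @param model A `pv_model` of family `"rf"` from [train_rf()], or a
#'   `randomForest` fit trained with `keep.forest = TRUE` and
#'   `keep.inbag = TRUE`.
#' @param data The training feature table the forest was fitted on (tibble
#'   or matrix, feature columns only, same column order).
#' @param labels The training class labels.
#' @return A tibble `feature`, `importance`, `rank`, sorted by decreasing
#'   importance (ties broken by schema order).
#' @export
gini_importance <- function(model, data, labels) {
  rf <- if (inherits(model, "pv_model")) model$fit else model
  if (!inherits(rf, "randomForest")) {
    abort("`model` must be a random forest.",
          class = "painvol_validation_error")
  }
  if (is.null(rf$inbag) || is.null(rf$forest)) {
    abort("Forest lacks stored node statistics (need keep.inbag and keep.forest).",
          class = "painvol_validation_error")
  }
  x <- as.matrix(as.data.frame(data))
  y <- as.integer(class_factor(labels))
  if (nrow(x) != length(y) || nrow(x) != nrow(rf$inbag)) {
    abort("`data`/`labels` do not match the forest's training size.",
          class = "painvol_validation_error")
  }
  p <- ncol(x)
  ntree <- rf$ntree
  imp <- numeric(p)
  for (t in seq_len(ntree)) {
    tr <- randomForest::getTree(rf, t, labelVar = FALSE)
    w <- rf$inbag[, t]
    n_total <- sum(w)
    node_members <- vector("list", nrow(tr))
    node_members[[1L]] <- which(w > 0L)
    for (j in seq_len(nrow(tr))) {
      if (tr[j, "status"] != 1L) next
      idx <- node_members[[j]]
      if (is.null(idx) || length(idx) == 0L) next
      v <- tr[j, "split var"]
      go_left <- x[idx, v] <= tr[j, "split point"]
      left <- idx[go_left]
      right <- idx[!go_left]
      node_members[[tr[j, "left daughter"]]] <- left
      node_members[[tr[j, "right daughter"]]] <- right
      wp <- w[idx]
      n_p <- sum(wp)
      n1 <- sum(wp[y[idx] == 1L])
      g_parent <- 1 - (n1 / n_p)^2 - (1 - n1 / n_p)^2
      n_l <- sum(w[left])
      n_r <- n_p - n_l
      g_l <- if (n_l > 0) {
        l1 <- sum(w[left][y[left] == 1L])
        1 - (l1 / n_l)^2 - (1 - l1 / n_l)^2
      } else 0
      g_r <- if (n_r > 0) {
        r1 <- sum(w[right][y[right] == 1L])
        1 - (r1 / n_r)^2 - (1 - r1 / n_r)^2
      } else 0
      imp[v] <- imp[v] +
        (n_p / n_total) * (g_parent - (n_l / n_p) * g_l - (n_r / n_p) * g_r)
      node_members[j] <- list(NULL)  # free; [[<- NULL would shift indices
    }
  }
  imp <- imp / ntree
  tibble(feature = colnames(x), importance = imp) |>
    arrange(dplyr::desc(.data$importance)) |>
    mutate(rank = dplyr::row_number())
}

# Default Boruta importance: out-of-bag permutation importance (mean
# decrease in accuracy) from a small random forest.
ranger_mda <- function(data, labels, seed, n_trees = 50L) {
  fit <- ranger::ranger(y = class_factor(labels), x = as.data.frame(data),
                        num.trees = n_trees, importance = "permutation",
                        num.threads = 1L, seed = seed)
  fit$variable.importance
}

#' Boruta all-relevant feature selection
#'
#' Implements the shadow-feature wrapper: each iteration augments the data
#' with an independently permuted copy ("shadow") of every undecided
#' feature (padded to a minimum of 5 shadows when few features remain
#' active), computes a mean-decrease-accuracy importance on the extended
#' set, and scores a *hit* for each feature whose importance exceeds the
#' best shadow importance. After every iteration a two-sided binomial test
#' (hit probability 1/2, Bonferroni-corrected for the number of still
#' undecided features) promotes features to `important` or demotes them to
#' `unimportant`; demoted features and their shadows leave the data.
#' Features still undecided after `max_iter` iterations are `tentative`.
#'
#' @param data Feature table (tibble/data frame/matrix), at least 2 columns.
#' @param labels Binary class labels.
#' @param importance_fn Function `(data, labels, seed) -> named numeric`
#'   returning a mean-decrease-accuracy importance per column of `data`.
#'   Defaults to out-of-bag permutation importance from a
#'   [ranger::ranger()] forest with `n_trees` trees.
#' @param max_iter Maximum iterations (at least 5).
#' @param alpha Significance level of the binomial decisions.
#' @param seed Integer seed (shadows and forests derive child seeds).
#' @param n_trees Trees per forest for the default importance function.
#' @return A `pv_boruta` object: tibble `decisions` (`feature`, `status`,
#'   `hits`, `runs`), `iterations`, `alpha`.
#' @export
boruta <- function(data, labels, importance_fn = NULL, max_iter = 50L,
                   alpha = 0.05, seed = 1L, n_trees = 50L) {
  max_iter <- assert_count(max_iter, "max_iter", min = 5L)
  assert_scalar_number(alpha, "alpha", 0, 1)
  x <- as.data.frame(data)
  if (ncol(x) < 2L) {
    abort("Boruta needs at least 2 features.",
          class = "painvol_validation_error")
  }
  if (is.null(importance_fn)) {
    importance_fn <- function(d, l, s) ranger_mda(d, l, s, n_trees = n_trees)
  }
  features <- colnames(x)
  status <- stats::setNames(rep("tentative", ncol(x)), features)
  hits <- stats::setNames(integer(ncol(x)), features)
  runs <- stats::setNames(integer(ncol(x)), features)
  seeds <- derive_seeds(seed, 2L * max_iter)
  iter <- 0L
  while (iter < max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    active <- names(status)[status != "unimportant"]
    xa <- x[, active, drop = FALSE]
    # at least 5 shadows (padding with extra permuted copies when few
    # features remain active), as in the published algorithm: a too-small
    # shadow pool makes its maximum a weak reference
    shadow_src <- active[((seq_len(max(5L, length(active))) - 1L) %%
                            length(active)) + 1L]
    shadows <- withr::with_seed(seeds[iter], {
      as.data.frame(lapply(x[, shadow_src, drop = FALSE], sample))
    })
    shadow_names <- paste0(".shadow_", seq_along(shadow_src))
    colnames(shadows) <- shadow_names
    imp <- importance_fn(cbind(xa, shadows), labels, seeds[max_iter + iter])
    if (any(!is.finite(imp))) {
      abort("Importance function returned non-finite values.",
            class = "painvol_validation_error")
    }
    shadow_max <- max(imp[shadow_names])
    hit <- imp[active] > shadow_max
    undecided <- names(status)[status == "tentative"]
    hits[undecided] <- hits[undecided] + as.integer(hit[undecided])
    runs[undecided] <- runs[undecided] + 1L
    n_undec <- length(undecided)
    for (f in undecided) {
      p_two <- min(1, 2 * min(
        pbinom(hits[f] - 1L, runs[f], 0.5, lower.tail = FALSE),
        pbinom(hits[f], runs[f], 0.5)))
      if (p_two * n_undec < alpha) {
        status[f] <- if (hits[f] * 2L > runs[f]) "important" else "unimportant"
      }
    }
  }
  structure(
    list(decisions = tibble(feature = features,
                            status = unname(status[features]),
                            hits = unname(hits[features]),
                            runs = unname(runs[features])),
         iterations = iter, alpha = alpha, seed = seed),
    class = "pv_boruta")
}

#' @export
print.pv_boruta <- function(x, ...) {
  tab <- table(factor(x$decisions$status,
                      levels = c("important", "tentative", "unimportant")))
  cat(sprintf(
    "<pv_boruta> %d iterations: %d important, %d tentative, %d unimportant\n",
    x$iterations, tab[["important"]], tab[["tentative"]],
    tab[["unimportant"]]))
  invisible(x)
}

#' @export
tidy.pv_boruta <- function(x, ...) x$decisions

# Largest-relative-drop elbow: cut a sorted score vector after the position
# with the biggest relative successive drop (searched over the top half,
# at most the top 20 positions).
elbow_cut <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  upper <- min(length(s) - 1L, 20L)
  if (upper < 1L) return(length(s))
  drops <- (s[seq_len(upper)] - s[seq_len(upper) + 1L]) /
    pmax(s[seq_len(upper)], .Machine$double.eps)
  which.max(drops)
}

#' Consensus feature selection across the training-set grid
#'
#' Applies three importance methods to every balanced training set in the
#' grid: (1) Gini mean-decrease-impurity from a random forest, (2)
#' information gain, and (3) Boruta. For the two ranking methods a top set
#' is taken per training set (fixed size, or automatic elbow detection with
#' `"elbow"`); Boruta contributes its `important` features. Each method's
#' sets are intersected across all training sets, and the final consensus
#' list is the union of the three per-method intersections.
#'
#' @param features Feature tibble (`user_id` + feature columns), typically
#'   from [extract_features()].
#' @param labels Tibble `user_id`, `class` with the outcome classes.
#' @param grid A `pv_grid` from [build_training_grid()].
#' @param top_gini,top_ig Top-set size per training set for the Gini and
#'   information-gain rankings (defaults 11 and 8), or `"elbow"` for the
#'   largest-relative-drop rule.
#' @param n_trees Trees per forest for the Gini ranking.
#' @param boruta_n_trees Trees per Boruta iteration forest. Smaller than
#'   `n_trees` by default: each iteration only contributes a binary
#'   hit/miss per feature and the binomial decision aggregates evidence
#'   over iterations, so per-iteration importance noise averages out.
#' @param boruta_max_iter,alpha Boruta iteration cap and significance level.
#' @param seed Master seed; per-set child seeds are derived from it.
#' @return A `pv_consensus` object: `selected` (final union, in schema
#'   order), `per_method` (list of the three intersections), `rankings`
#'   (tibble `set_id`, `fold`, `subsample`, `method`, `feature`, `score`,
#'   `rank`) and `boruta` (per-set decisions).
#' @export
consensus_select <- function(features, labels, grid,
                             top_gini = 11L, top_ig = 8L,
                             n_trees = 50L, boruta_n_trees = 30L,
                             boruta_max_iter = 20L,
                             alpha = 0.05, seed = 1L) {
  feature_names <- setdiff(names(features), "user_id")
  lab <- labels[match(features$user_id, labels$user_id), ]
  # child seeds are keyed to the (fold, subsample) cell, not the row
  # position, so the report is invariant to the order of the grid rows
  n_cells <- max(grid$fold) * max(grid$subsample)
  seeds_all <- derive_seeds(seed, 2L * n_cells)
  cell <- (grid$fold - 1L) * max(grid$subsample) + grid$subsample
  seeds <- seeds_all[cell]
  seeds_bor <- seeds_all[n_cells + cell]
  rankings <- vector("list", nrow(grid))
  boruta_sets <- vector("list", nrow(grid))
  gini_sets <- ig_sets <- bor_sets <- vector("list", nrow(grid))

  for (i in seq_len(nrow(grid))) {
    idx <- match(grid$users[[i]], features$user_id)
    x <- features[idx, feature_names]
    y <- class_factor(lab$class[idx])

    rf <- train_rf(x, y, n_trees = n_trees, seed = seeds[i])
    g <- gini_importance(rf, x, y)
    k_g <- if (identical(top_gini, "elbow")) elbow_cut(g$importance)
           else assert_count(top_gini, "top_gini")
    gini_sets[[i]] <- g$feature[seq_len(min(k_g, nrow(g)))]

    ig_scores <- vapply(feature_names,
                        function(f) information_gain(x[[f]], y),
                        numeric(1))
    ig_tbl <- tibble(feature = feature_names, importance = ig_scores) |>
      arrange(dplyr::desc(.data$importance)) |>
      mutate(rank = dplyr::row_number())
    k_i <- if (identical(top_ig, "elbow")) elbow_cut(ig_tbl$importance)
           else assert_count(top_ig, "top_ig")
    ig_sets[[i]] <- ig_tbl$feature[seq_len(min(k_i, nrow(ig_tbl)))]

    bor <- boruta(x, y, max_iter = boruta_max_iter, alpha = alpha,
                  seed = seeds_bor[i], n_trees = boruta_n_trees)
    bor_sets[[i]] <- bor$decisions$feature[bor$decisions$status == "important"]
    boruta_sets[[i]] <- mutate(bor$decisions,
                               set_id = i, fold = grid$fold[i],
                               subsample = grid$subsample[i])

    rankings[[i]] <- dplyr::bind_rows(
      mutate(g, method = "gini"),
      mutate(ig_tbl, method = "info_gain")) |>
      mutate(set_id = i, fold = grid$fold[i], subsample = grid$subsample[i])
  }

  per_method <- list(
    gini = Reduce(intersect, gini_sets),
    info_gain = Reduce(intersect, ig_sets),
    boruta = Reduce(intersect, bor_sets))
  # canonical order: the schema's, so reports do not depend on grid order
  per_method <- lapply(per_method,
                       function(fs) feature_names[feature_names %in% fs])
  for (m in names(per_method)) {
    if (length(per_method[[m]]) == 0L) {
      warn(sprintf("Method '%s' has an empty consensus intersection.", m))
    }
  }
  selected <- feature_names[feature_names %in%
                              unique(unlist(per_method, use.names = FALSE))]
  structure(
    list(selected = selected, per_method = per_method,
         rankings = dplyr::bind_rows(rankings),
         boruta = dplyr::bind_rows(boruta_sets),
         config = list(top_gini = top_gini, top_ig = top_ig,
                       n_trees = n_trees, boruta_n_trees = boruta_n_trees,
                       boruta_max_iter = boruta_max_iter,
                       alpha = alpha, seed = seed)),
    class = "pv_consensus")
}

#' @export
print.pv_consensus <- function(x, ...) {
  cat(sprintf(
    "<pv_consensus> %d features selected (gini %d, info_gain %d, boruta %d)\n",
    length(x$selected), length(x$per_method$gini),
    length(x$per_method$info_gain), length(x$per_method$boruta)))
  cat(paste0("  ", paste(x$selected, collapse = ", "), "\n"))
  invisible(x)
}

#' @export
tidy.pv_consensus <- function(x, ...) {
  purrr::imap(x$per_method, function(fs, m) {
    tibble(method = m, feature = fs)
  }) |>
    dplyr::bind_rows() |>
    mutate(selected = TRUE) |>
    tidyr::pivot_wider(names_from = "method", values_from = "selected",
                       values_fill = FALSE) |>
    mutate(consensus = .data$feature %in% x$selected)
}

#' @export
glance.pv_consensus <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_gini = length(x$per_method$gini),
         n_info_gain = length(x$per_method$info_gain),
         n_boruta = length(x$per_method$boruta),
         n_sets = length(unique(x$rankings$set_id)))
}
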