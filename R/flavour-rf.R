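# Random-forest permutation importance. The forest itself is a standard
# randomForest regression fit; the importance statistic is computed here:
# for each tree, each feature is permuted within the tree's out-of-bag
# rows (the permutations are recorded on the returned object so they can
# be replayed), and
#   %IncMSE = 100 * mean_t(OOB MSE after permuting - OOB MSE before)
#                 / baseline OOB MSE of the forest,
# i.e. the literal percentage increase in mean squared error, not the
# sd-scaled z-score some implementations report under the same name.

#' Permutation importance of features for one response
#'
#' Fits a regression random forest (`n_trees` trees, bootstrap resampling,
#' random feature subsetting at each split) and computes the percentage
#' increase in out-of-bag mean squared error (%IncMSE) caused by permuting
#' each feature within each tree's out-of-bag set. All randomness (forest
#' and permutations) is governed by `seed`; the per-tree permutations and
#' in-bag matrix are recorded so importances can be re-derived exactly.
#'
#' @param x Data frame or matrix of numeric features (instances x
#'   features), at least 5 instances.
#' @param y Numeric response vector (one sensory attribute).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried at each split (default `max(p/3, 1)`).
#' @param seed Integer seed.
#' @return An `rf_importance` object: named `importance` (%IncMSE),
#'   `baseline_mse` (forest OOB MSE), `oob_r_squared`, the fitted
#'   `forest`, the recorded `permutations` (per feature, per tree) and
#'   `seed`.
#' @export
rf_importance <- function(x, y, n_trees = 500, mtry = NULL, seed = 1L) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 5) stop("need at least 5 instances", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete", call. = FALSE)
  feat <- colnames(x)

  if (var(y) == 0) {
    warning("constant response: all importances defined as 0", call. = FALSE)
    return(structure(list(
      importance = setNames(rep(0, length(feat)), feat),
      baseline_mse = 0, oob_r_squared = NA_real_, forest = NULL,
      permutations = NULL, seed = seed
    ), class = "rf_importance"))
  }
  if (is.null(mtry)) mtry <- max(floor(length(feat) / 3), 1)

  with_seed(seed, {
    rf <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = mtry,
      importance = FALSE, keep.forest = TRUE, keep.inbag = TRUE
    )
    oob_rows <- lapply(seq_len(n_trees), function(t) which(rf$inbag[, t] == 0))
    perms <- lapply(feat, function(j) {
      lapply(oob_rows, function(rows) sample.int(length(rows)))
    })
    names(perms) <- feat
  })

  baseline <- mean((rf$predicted - y)^2, na.rm = TRUE)
  # trees whose bootstrap sample covered every row have no OOB set and
  # cannot contribute to the permutation average
  t_ok <- lengths(oob_rows) > 0
  base_pred <- predict(rf, x, predict.all = TRUE)$individual
  mse_base <- vapply(seq_len(n_trees), function(t) {
    rows <- oob_rows[[t]]
    if (length(rows) == 0) return(NA_real_)
    mean((base_pred[rows, t] - y[rows])^2)
  }, numeric(1))

  xm <- as.matrix(x)
  importance <- vapply(feat, function(j) {
    # stack every tree's permuted OOB rows into one prediction call
    blocks <- lapply(seq_len(n_trees), function(t) {
      rows <- oob_rows[[t]]
      xb <- xm[rows, , drop = FALSE]
      xb[, j] <- xb[perms[[j]][[t]], j]
      xb
    })
    stacked <- as.data.frame(do.call(rbind, blocks))
    pred <- predict(rf, stacked, predict.all = TRUE)$individual
    offsets <- cumsum(c(0L, vapply(oob_rows, length, integer(1))))
    mse_perm <- vapply(seq_len(n_trees), function(t) {
      rows <- oob_rows[[t]]
      if (length(rows) == 0) return(NA_real_)
      idx <- (offsets[t] + 1L):offsets[t + 1L]
      mean((pred[idx, t] - y[rows])^2)
    }, numeric(1))
    100 * mean(mse_perm[t_ok] - mse_base[t_ok]) / baseline
  }, numeric(1))

  structure(list(
    importance = importance,
    baseline_mse = baseline,
    oob_r_squared = 1 - baseline / mean((y - mean(y))^2),
    forest = rf,
    oob_rows = oob_rows,
    per_tree_mse = mse_base,
    permutations = perms,
    seed = seed
  ), class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat("Random-forest permutation importance (%IncMSE)\n")
  cat(sprintf("  baseline OOB MSE %.4g, OOB R^2 %.3f\n",
              x$baseline_mse, x$oob_r_squared))
  print(round(sort(x$importance, decreasing = TRUE), 2))
  invisible(x)
}

#' @export
tidy.rf_importance <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 inc_mse_pct = unname(x$importance))
}

#' @export
glance.rf_importance <- function(x, ...) {
  tibble::tibble(baseline_mse = x$baseline_mse,
                 oob_r_squared = x$oob_r_squared,
                 n_trees = if (is.null(x$forest)) NA_integer_ else x$forest$ntree,
                 seed = x$seed)
}

#' Feature importance for every sensory attribute
#'
#' Fits one permutation-importance forest ([rf_importance()]) per sensory
#' attribute over a shared feature matrix (typically the cluster
#' representatives) and collects the %IncMSE values into an attribute x
#' feature map.
#'
#' @param features Data frame of instances x features; non-numeric columns
#'   are dropped.
#' @param sensory Data frame of instances x sensory attributes (scores
#'   0-10), same row order as `features`; non-numeric columns are dropped.
#' @inheritParams rf_importance
#' @return An `importance_map` object: the `importance` matrix (attributes
#'   in rows), per-attribute `oob_r_squared`, per-model seeds and the
#'   fitted `models`.
#' @export
flavour_importance <- function(features, sensory, n_trees = 500, mtry = NULL,
                               seed = 1L) {
  x <- dplyr::select(tibble::as_tibble(features), dplyr::where(is.numeric))
  ys <- dplyr::select(tibble::as_tibble(sensory), dplyr::where(is.numeric))
  if (nrow(x) != nrow(ys)) {
    stop("features and sensory tables must have the same instances",
         call. = FALSE)
  }
  if (any(as.matrix(ys) < 0 | as.matrix(ys) > 10)) {
    stop("sensory scores must lie in [0, 10]", call. = FALSE)
  }
  attrs <- names(ys)
  seeds <- vapply(attrs, function(a) derive_seed(seed, "rf", a), integer(1))
  models <- purrr::map2(attrs, seeds, function(a, s) {
    rf_importance(x, ys[[a]], n_trees = n_trees, mtry = mtry, seed = s)
  })
  names(models) <- attrs
  imp <- do.call(rbind, lapply(models, function(m) m$importance))
  rownames(imp) <- attrs
  structure(list(
    importance = imp,
    oob_r_squared = vapply(models, function(m) m$oob_r_squared, numeric(1)),
    seeds = seeds,
    models = models
  ), class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("Importance map: %d attributes x %d features (%%IncMSE)\n",
              nrow(x$importance), ncol(x$importance)))
  print(round(x$importance, 2))
  invisible(x)
}

#' @export
tidy.importance_map <- function(x, ...) {
  out <- tibble::as_tibble(x$importance, rownames = "attribute")
  tidyr::pivot_longer(out, -"attribute", names_to = "feature",
                      values_to = "inc_mse_pct")
}

#' @export
autoplot.importance_map <- function(object, ...) {
  imp <- object$importance
  # mirror the heat-map convention: Ward ordering of rows and columns on
  # Euclidean distances of the importance profiles
  ord_r <- if (nrow(imp) > 2) {
    stats::hclust(stats::dist(imp), method = "ward.D2")$order
  } else {
    seq_len(nrow(imp))
  }
  ord_c <- if (ncol(imp) > 2) {
    stats::hclust(stats::dist(t(imp)), method = "ward.D2")$order
  } else {
    seq_len(ncol(imp))
  }
  long <- tidy(object)
  long$attribute <- factor(long$attribute, levels = rownames(imp)[ord_r])
  long$feature <- factor(long$feature, levels = colnames(imp)[ord_c])
  ggplot2::ggplot(long, ggplot2::aes(.data$feature, .data$attribute,
                                     fill = .data$inc_mse_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "%IncMSE") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
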