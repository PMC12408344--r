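# Redundancy reduction for the kinetic feature matrix: pairwise Pearson
# correlation with t-transform p-values, Ward (ward.D2) clustering of the
# feature-wise correlation vectors, and one representative per cluster by
# highest coefficient of variation.

#' Min-max rescale numeric columns to [0, 1]
#'
#' Per column: `(x - min) / (max - min)`. Constant columns map to 0.
#' Non-numeric columns are passed through unchanged, so identifier columns
#' can stay in place.
#'
#' @param data Data frame.
#' @return Tibble with numeric columns rescaled; idempotent.
#' @examples
#' rescale01(data.frame(x = c(2, 4, 6)))
#' @export
rescale01 <- function(data) {
  dplyr::mutate(tibble::as_tibble(data),
    dplyr::across(dplyr::where(is.numeric), function(x) {
      if (anyNA(x) || any(!is.finite(x))) {
        stop("columns must be finite before rescaling", call. = FALSE)
      }
      rng <- range(x)
      if (rng[1] == rng[2]) return(rep(0, length(x)))
      (x - rng[1]) / (rng[2] - rng[1])
    })
  )
}

# Two-sided p-value of a Pearson correlation via the t transform
# t = r sqrt((n-2) / (1-r^2)) against the t distribution with n-2 df.
pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Correlation clustering of features
#'
#' Computes the pairwise Pearson correlation and two-sided p-value
#' matrices over the numeric feature columns, then clusters features by
#' Ward linkage (`ward.D2`) on Euclidean distances between feature-wise
#' correlation vectors. The tree is cut at `k` clusters or height `h`;
#' with neither given, `k` defaults to the cut maximizing the mean
#' silhouette width over `k` in `[2, n_features - 1]`. One representative
#' per cluster is chosen as the member with the highest coefficient of
#' variation (sample sd / mean, computed on the raw pre-rescaling values);
#' ties break to the lexicographically first feature name, and zero-mean
#' features (undefined CV) are deprioritized.
#'
#' @param data Data frame of instances x features; non-numeric columns are
#'   treated as identifiers and ignored.
#' @param k Number of clusters (optional).
#' @param h Tree cut height (optional, ignored when `k` is given).
#' @return A `feature_clusters` object: correlation matrix `r`, p-value
#'   matrix `p`, the `hclust` tree, integer `clusters` assignment, `cv`
#'   per feature, the chosen `k`, and `representatives`.
#' @export
cluster_features <- function(data, k = NULL, h = NULL) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(data),
                               dplyr::where(is.numeric)))
  if (ncol(x) < 2) stop("need at least 2 features", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 instances", call. = FALSE)
  vars <- apply(x, 2, var)
  if (any(vars == 0)) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(x)[vars == 0], collapse = ", "), call. = FALSE)
    x <- x[, vars > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 features remain", call. = FALSE)
  }

  r <- cor(x)
  p <- pearson_p(r, nrow(x))
  diag(p) <- 0

  d <- stats::dist(r)
  tree <- stats::hclust(d, method = "ward.D2")

  nf <- ncol(x)
  if (is.null(k) && is.null(h)) {
    ks <- seq(2L, max(2L, nf - 1L))
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(tree, k = kk)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  clusters <- if (!is.null(k)) {
    stats::cutree(tree, k = min(k, nf))
  } else {
    stats::cutree(tree, h = h)
  }

  cv <- apply(x, 2, function(col) {
    m <- mean(col)
    if (m == 0) NA_real_ else sd(col) / m
  })
  if (anyNA(cv)) {
    warning("zero-mean feature(s) have undefined CV and are deprioritized: ",
            paste(names(cv)[is.na(cv)], collapse = ", "), call. = FALSE)
  }

  reps <- vapply(sort(unique(clusters)), function(cl) {
    members <- sort(names(clusters)[clusters == cl])
    cvs <- cv[members]
    if (all(is.na(cvs))) return(members[1])
    best <- max(cvs, na.rm = TRUE)
    members[!is.na(cvs) & cvs == best][1]
  }, character(1))

  structure(list(
    r = r, p = p, tree = tree, clusters = clusters, cv = cv,
    k = length(unique(clusters)), representatives = unname(reps)
  ), class = "feature_clusters")
}

#' @export
print.feature_clusters <- function(x, ...) {
  cat(sprintf("Feature correlation clustering: %d features in %d clusters\n",
              length(x$clusters), x$k))
  cat("representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.feature_clusters <- function(x, ...) {
  tibble::tibble(
    feature = names(x$clusters),
    cluster = unname(x$clusters),
    cv = unname(x$cv[names(x$clusters)]),
    representative = names(x$clusters) %in% x$representatives
  )
}

#' Representative features of a clustering
#'
#' @param clusters A `feature_clusters` object.
#' @return Character vector with one feature per cluster (highest CV,
#'   ties to the lexicographically first name).
#' @export
select_representatives <- function(clusters) {
  stopifnot(inherits(clusters, "feature_clusters"))
  clusters$representatives
}
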