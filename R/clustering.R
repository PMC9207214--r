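#' Cluster migration features by k-means with a fixed k
#'
#' Clusters tracks in the 2-D migration feature space (total distance
#' migrated, number of direction changes) with Lloyd's algorithm, seeded by
#' k-means++-style initialization and restarted `n_restarts` times; the fit
#' with the lowest within-cluster sum of squares (WCSS) wins. The whole
#' procedure is deterministic given `(seed, n_restarts)`.
#'
#' Distances run to hundreds of micrometres while change counts stay in
#' single digits, so raw Euclidean distance is dominated by the distance
#' axis; by default both features are z-standardized before clustering
#' (`standardize = FALSE` reproduces the unscaled behavior). Centroids are
#' reported in the original feature units either way.
#'
#' @param features Data frame with columns `total_distance` and
#'   `n_direction_changes` (e.g. from [featurize_tracks()]), or a two-column
#'   numeric matrix.
#' @param k Number of clusters; must not exceed the number of tracks.
#' @param seed Integer seed.
#' @param n_restarts Independent k-means++ restarts. Default 20.
#' @param standardize Z-standardize both features first. Default `TRUE`.
#' @return An object of class `cluster_result`: list with `k`, `labels`
#'   (1-based integer per track), `centroids` (k x 2, original units),
#'   `wcss`, `wcss_curve` (`NULL` for a fixed-k fit), `seed`, `n_restarts`,
#'   `standardized`.
#' @export
kmeans_fit <- function(features, k, seed = 1, n_restarts = 20,
                       standardize = TRUE) {
  X <- feature_matrix(features)
  check_number(k, "k", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  check_number(n_restarts, "n_restarts", lower = 1, integerish = TRUE)
  if (k > nrow(X)) abort("`k` cannot exceed the number of tracks")
  ctr <- c(0, 0)
  scl <- c(1, 1)
  Xs <- X
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sample_sd)
    scl[scl == 0] <- 1  # constant feature: leave centered but unscaled
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  distinct <- unique(Xs)
  if (k >= nrow(distinct)) {
    # more clusters than distinct points: the optimum is exact — every
    # distinct point its own centroid, zero WCSS (padding duplicates the
    # first point so the centroid count stays k)
    labels <- match(apply(Xs, 1, paste, collapse = "\r"),
                    apply(distinct, 1, paste, collapse = "\r"))
    centers <- distinct[c(seq_len(nrow(distinct)),
                          rep(1L, k - nrow(distinct))), , drop = FALSE]
    fit <- list(cluster = labels, centers = centers, tot.withinss = 0)
  } else {
    fit <- withr::with_seed(seed, best_of_restarts(Xs, k, n_restarts))
  }
  centroids <- sweep(sweep(fit$centers, 2, scl, "*"), 2, ctr, "+")
  colnames(centroids) <- colnames(X)
  structure(
    list(k = as.integer(k), labels = as.integer(fit$cluster),
         centroids = centroids, wcss = fit$tot.withinss,
         wcss_curve = NULL, seed = as.integer(seed),
         n_restarts = as.integer(n_restarts), standardized = standardize),
    class = "cluster_result"
  )
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    check_columns(features, c("total_distance", "n_direction_changes"),
                  "features")
    X <- cbind(total_distance = features$total_distance,
               n_direction_changes = features$n_direction_changes)
  } else {
    X <- as.matrix(features)
    if (ncol(X) != 2L) abort("feature matrix must have exactly two columns")
    if (is.null(colnames(X))) {
      colnames(X) <- c("total_distance", "n_direction_changes")
    }
  }
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("features must be finite numbers")
  }
  if (nrow(X) < 1L) abort("no tracks to cluster")
  X
}

# Best of n k-means++-seeded Lloyd fits by total within-cluster SS.
# Consumes the ambient RNG stream (caller fixes the seed).
best_of_restarts <- function(X, k, n_restarts) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(X, k)
    fit <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L,
                                       algorithm = "Lloyd"))
      }
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed on every restart; check the features")
  best
}

# k-means++ seeding: first center uniform, then points with probability
# proportional to squared distance from the nearest chosen center. Duplicate
# points are never chosen twice, so centers stay distinct.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        # every remaining point coincides with a chosen center
        abort("`k` exceeds the number of distinct feature points")
      }
      idx[j] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

#' Select the cluster count by the elbow method
#'
#' Fits k-means for `k = 1 .. k_max`, records the WCSS curve, and selects
#' the k with the largest second difference of the curve
#' (`wcss[k-1] - 2 wcss[k] + wcss[k+1]`, the discrete curvature), i.e. the
#' sharpest bend — an automated reading of the visual elbow. Ties go to the
#' smallest k. The full curve is returned for audit.
#'
#' @inheritParams kmeans_fit
#' @param k_max Largest k fitted. Default 8. At least 3 tracks are required;
#'   `k_max` is capped at the number of tracks.
#' @return A `cluster_result` (see [kmeans_fit()]) at the selected k, with
#'   `wcss_curve` filled with the WCSS for `k = 1 .. k_max`.
#' @export
elbow_select_k <- function(features, k_max = 8, seed = 1, n_restarts = 20,
                           standardize = TRUE) {
  X <- feature_matrix(features)
  check_number(k_max, "k_max", lower = 3, integerish = TRUE)
  if (nrow(X) < 3L) abort("elbow selection needs at least 3 tracks")
  k_max <- min(k_max, nrow(X))
  fits <- lapply(seq_len(k_max), function(k) {
    kmeans_fit(X, k, seed = seed, n_restarts = n_restarts,
               standardize = standardize)
  })
  wcss <- vapply(fits, function(f) f$wcss, numeric(1))
  ks <- 2:(k_max - 1)
  d2 <- wcss[ks - 1] - 2 * wcss[ks] + wcss[ks + 1]
  best_k <- ks[which.max(d2)]  # which.max takes the first = smallest k on ties
  out <- fits[[best_k]]
  out$wcss_curve <- stats::setNames(wcss, paste0("k", seq_len(k_max)))
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, WCSS = %.4g (%s features, seed %d, %d restarts)\n",
              x$k, x$wcss, if (x$standardized) "standardized" else "raw",
              x$seed, x$n_restarts))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same tracks,
#' in `[-1, 1]` with 1 for identical partitions (up to label renaming).
#'
#' @param labels_a,labels_b Vectors of equal length.
#' @return The adjusted Rand index.
#' @export
cluster_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("labelings must have the same length")
  }
  if (!length(labels_a)) abort("labelings are empty")
  mclust::adjustedRandIndex(labels_a, labels_b)
}
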