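#' k-means clustering of z-scored expression profiles
#'
#' Best-of-`n_init` k-means (Euclidean distance over time points) with a
#' fixed RNG stream, so results are reproducible given the seed. Input rows
#' must be z-scored, non-degenerate profiles.
#'
#' @param z Numeric matrix of z-scored profiles (rows = genes, columns = time
#'   points, rownames = gene ids), or a wide profile table.
#' @param k Number of clusters (pipeline default in this package: 6).
#' @param seed Integer seed.
#' @param n_init Random restarts (default 25).
#' @param warm_centers Optional centroid matrix (< k rows allowed) used as an
#'   additional warm start, augmented with the observation farthest from its
#'   centroid; [wss_curve()] chains these so the WSS curve is non-increasing.
#' @return List of class `cluster_result`: `labels` (named integer vector),
#'   `centroids` (k x T matrix of mean member profiles), `wss` (total
#'   within-cluster sum of squares), `k`, `seed`.
#' @export
kmeans_profiles <- function(z, k, seed = 7L, n_init = 25L,
                            warm_centers = NULL) {
  if (is.data.frame(z)) z <- profile_matrix(z)
  stopifnot(is.matrix(z), k >= 1L)
  if (k > nrow(z))
    stop2("bad_k", "k (%d) exceeds the number of profiles (%d)", k, nrow(z))
  km <- withr::with_seed(as.integer(seed) + as.integer(k), {
    fit <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100L)
    if (!is.null(warm_centers) && nrow(warm_centers) <= k) {
      centers <- warm_centers
      while (nrow(centers) < k) {
        assign <- apply(z, 1L, function(r)
          which.min(colSums((t(centers) - r)^2)))
        far <- which.max(rowSums((z - centers[assign, , drop = FALSE])^2))
        centers <- rbind(centers, z[far, ])
      }
      warm <- tryCatch(stats::kmeans(z, centers = centers, iter.max = 100L),
                       error = function(e) NULL)
      if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
    }
    fit
  })
  centroids <- km$centers
  rownames(centroids) <- seq_len(k)
  structure(list(labels = stats::setNames(km$cluster, rownames(z)),
                 centroids = centroids, wss = km$tot.withinss,
                 k = k, seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means: k = %d, %d profiles, total WSS = %.4g\n",
              x$k, length(x$labels), x$wss))
  invisible(x)
}

#' Within-cluster sum-of-squares curve over a range of k
#'
#' Used to choose k by the elbow criterion: the curve is non-increasing, and
#' a k beyond which additional clusters no longer greatly reduce the total
#' intra-cluster variation is appropriate. `elbow_k()` automates this as the
#' k with the maximum second difference of the curve.
#'
#' @param z z-scored profile matrix (or wide table).
#' @param k_range Integer vector of k values.
#' @param seed,n_init As in [kmeans_profiles()].
#' @return Data frame with columns `k` and `wss`.
#' @export
wss_curve <- function(z, k_range, seed = 7L, n_init = 25L) {
  if (is.data.frame(z)) z <- profile_matrix(z)
  k_range <- sort(as.integer(k_range))
  wss <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    res <- kmeans_profiles(z, k_range[i], seed = seed, n_init = n_init,
                           warm_centers = prev)
    wss[i] <- res$wss
    prev <- res$centroids
  }
  data.frame(k = k_range, wss = wss)
}

#' Elbow of a WSS curve
#'
#' @param curve Data frame from [wss_curve()] with consecutive k.
#' @return The k maximizing the second difference of WSS.
#' @export
elbow_k <- function(curve) {
  stopifnot(nrow(curve) >= 3L)
  d2 <- diff(curve$wss, differences = 2L)
  curve$k[which.max(d2) + 1L]
}

#' Pearson correlation between two sets of cluster centroids
#'
#' @param centroids_a,centroids_b Matrices of centroid profiles on the same
#'   time grid (rows = clusters).
#' @return `nrow(a) x nrow(b)` matrix of Pearson correlations; constant
#'   centroids give `NA` entries.
#' @export
centroid_correlation <- function(centroids_a, centroids_b) {
  stopifnot(ncol(centroids_a) == ncol(centroids_b))
  out <- matrix(NA_real_, nrow(centroids_a), nrow(centroids_b))
  for (i in seq_len(nrow(centroids_a))) {
    if (sd_pop(centroids_a[i, ]) < 1e-12) next
    for (j in seq_len(nrow(centroids_b))) {
      if (sd_pop(centroids_b[j, ]) < 1e-12) next
      out[i, j] <- stats::cor(centroids_a[i, ], centroids_b[j, ])
    }
  }
  dimnames(out) <- list(rownames(centroids_a), rownames(centroids_b))
  out
}
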