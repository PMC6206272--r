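as_points_matrix <- function(points) {
  stages <- c("vegetative", "flowering", "maturation")
  if (is.data.frame(points)) {
    stopifnot(all(stages %in% names(points)))
    X <- as.matrix(points[, stages])
    rownames(X) <- if ("plant_id" %in% names(points)) points$plant_id
                   else as.character(seq_len(nrow(points)))
  } else {
    X <- as.matrix(points)
    if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  storage.mode(X) <- "double"
  X
}

#' K-means categorization of chemotype stage vectors
#'
#' Clusters plants on their raw three-stage fraction vectors (vegetative,
#' flowering, maturation, in percent -- all axes share units, so no
#' scaling is applied) with Euclidean k-means. The fit is delegated to
#' [stats::kmeans()] with `restarts` random starts under a fixed seed, so
#' results are reproducible; the best run by total within-cluster sum of
#' squares (WSS) is kept.
#'
#' @param points data.frame with columns plant_id, vegetative, flowering,
#'   maturation (e.g. from [stage_series()]), or a numeric matrix n x 3.
#' @param k Number of clusters, `1 <= k <=` number of distinct points.
#' @param seed Integer RNG seed.
#' @param restarts Number of random restarts (default 50).
#' @return Object of class `cluster_model`: k, centroids, assignments
#'   (named integer vector), wss, the points, and the seed. Class labels
#'   are added by [label_classes()].
#' @export
chemotype_kmeans <- function(points, k, seed = 1L, restarts = 50L) {
  X <- as_points_matrix(points)
  n_distinct <- nrow(unique(X))
  if (k < 1 || k > n_distinct) {
    stop(sprintf("k must be between 1 and the number of distinct points (%d)", n_distinct))
  }
  km <- with_preserved_seed(seed, {
    tryCatch(
      stats::kmeans(X, centers = k, nstart = restarts, iter.max = 300L),
      error = function(e) {
        stats::kmeans(X, centers = k, nstart = restarts, iter.max = 300L,
                      algorithm = "Lloyd")
      })
  })
  assignments <- km$cluster
  names(assignments) <- rownames(X)
  structure(
    list(k = k,
         centroids = km$centers,
         assignments = assignments,
         wss = km$tot.withinss,
         points = X,
         seed = seed,
         restarts = restarts,
         class_labels = NULL,
         class_ranges = NULL),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means chemotype model: k = %d, WSS = %.3f, n = %d\n",
              x$k, x$wss, nrow(x$points)))
  if (!is.null(x$class_labels)) {
    for (i in seq_len(x$k)) {
      rng <- x$class_ranges[[i]]
      cat(sprintf("  cluster %d [%s]: n = %d, maturation range %.2f-%.2f%%\n",
                  i, x$class_labels[[i]], sum(x$assignments == i), rng[1], rng[2]))
    }
  }
  invisible(x)
}

#' Criterion curve: best WSS as a function of k
#'
#' Runs seeded k-means for k = 1..k_max and records the best total
#' within-cluster sum of squares per k. The curve is made monotone
#' non-increasing by carrying forward the better of the k-1 and k
#' solutions where restarts under-perform (a k-partition can always
#' emulate a (k-1)-partition).
#'
#' @inheritParams chemotype_kmeans
#' @param k_max Largest k evaluated.
#' @return Named numeric vector, names "1".."k_max".
#' @export
criterion_curve <- function(points, k_max, seed = 1L, restarts = 50L) {
  X <- as_points_matrix(points)
  if (k_max > nrow(X)) stop("k_max exceeds number of points")
  wss <- vapply(seq_len(k_max), function(k) {
    chemotype_kmeans(X, k, seed = seed + k, restarts = restarts)$wss
  }, numeric(1))
  wss <- cummin(wss)
  names(wss) <- as.character(seq_len(k_max))
  wss
}

#' Elbow selection of the number of clusters
#'
#' Formalizes the visual elbow of a criterion-vs-k curve as the k with the
#' sharpest relative bend: the maximum second difference of log(WSS),
#' equivalently the k whose preceding WSS drop is largest relative to the
#' following one. Working on the log scale makes the rule scale-free, so
#' the elbow of (1000, 400, 100, 90, 85) is k = 3. Ties take the smaller
#' k. A curve with no pronounced bend (maximum log-curvature below 0.05)
#' is flagged low-confidence.
#'
#' @param curve Named numeric vector from [criterion_curve()] (>= 3 entries).
#' @return List: `k`, `second_differences` (log scale, one per interior k),
#'   `low_confidence`.
#' @export
select_k <- function(curve) {
  if (length(curve) < 3L) stop("criterion curve needs at least 3 entries")
  ks <- as.integer(names(curve) %||% seq_along(curve))
  if (is.null(names(curve))) names(curve) <- as.character(ks)
  eps <- max(curve) * 1e-12 + 1e-300
  L <- log(pmax(curve, eps))
  interior <- 2:(length(curve) - 1L)
  d <- L[interior - 1L] - 2 * L[interior] + L[interior + 1L]
  names(d) <- as.character(ks[interior])
  best <- which.max(d)  # which.max takes the first (smallest k) on ties
  list(k = ks[interior][best],
       second_differences = d,
       low_confidence = max(d) < 0.05)
}

#' Order clusters and attach chemotype class labels
#'
#' Orders clusters by the mean of their centroids and, for k = 3, labels
#' them low / intermediate / high (other k fall back to class_1..class_k).
#' The per-class range [min, max] of the maturation-stage fraction is
#' reported; ranges of adjacent classes may overlap, since cluster
#' boundaries live in the three-stage feature space, not on the maturation
#' axis alone.
#'
#' @param model A `cluster_model` from [chemotype_kmeans()].
#' @return The model with `class_labels` (cluster index -> label) and
#'   `class_ranges` (cluster index -> c(min, max) maturation %).
#' @export
label_classes <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  means <- rowMeans(model$centroids)
  ord <- order(means)  # rank of each cluster, ascending centroid mean
  labels <- character(model$k)
  base <- if (model$k == 3L) c("low", "intermediate", "high")
          else paste0("class_", seq_len(model$k))
  labels[ord] <- base
  ranges <- lapply(seq_len(model$k), function(i) {
    v <- model$points[model$assignments == i, "maturation"]
    c(min = min(v), max = max(v))
  })
  model$class_labels <- labels
  model$class_ranges <- ranges
  model
}
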