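## Ward clustering of the SOM units, silhouette model selection, cuts.

# Codebooks in the metric the map was trained in: each layer scaled by
# sqrt(w_l) so plain Euclidean distance equals the layer-weighted distance.
.weighted_codebook <- function(model) {
  xw <- model$codebook
  for (l in seq_along(model$layers))
    xw[, model$layers[[l]]] <- xw[, model$layers[[l]], drop = FALSE] *
      sqrt(model$layer_weights[l])
  xw
}

#' Ward hierarchical clustering of the SOM units
#'
#' Agglomerative Ward linkage (Ward.D2: each merge minimizes the increase
#' in total within-cluster variance; heights are `sqrt(2 * delta-SSE)`) on
#' Euclidean distances between the 27 codebook vectors in the normalized
#' (layer-weighted) feature space.
#'
#' @param model A `som_model`.
#' @return An object of class `"cluster_tree"`: list with `hclust` (the
#'   merge tree), `codebook_w` (weighted codebooks), `dist` (unit distance
#'   matrix), `n_units`.
#' @export
ward_tree <- function(model) {
  stopifnot(inherits(model, "som_model"))
  xw <- .weighted_codebook(model)
  if (any(!is.finite(xw))) stop("codebooks contain non-finite values")
  d <- dist(xw)
  structure(
    list(hclust = stats::hclust(d, method = "ward.D2"),
         codebook_w = xw, dist = as.matrix(d), n_units = nrow(xw)),
    class = "cluster_tree"
  )
}

#' Mean silhouette width of a partition
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is the mean distance
#' to its own cluster (excluding itself) and `b` the smallest mean distance
#' to another cluster; singletons score 0 by convention.
#'
#' @param d A distance matrix (full symmetric) or `dist` object.
#' @param labels Integer cluster labels.
#' @return Mean silhouette width over points.
#' @export
silhouette_width <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters")
  # mean distance from every point to every cluster, in one pass
  member <- vapply(ks, function(k) as.numeric(labels == k), numeric(n))
  sums <- d %*% member
  sizes <- colSums(member)
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], ks)
    if (sizes[k] == 1) { s[i] <- 0; next }
    a <- sums[i, k] / (sizes[k] - 1)
    b <- min(sums[i, -k] / sizes[-k])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette profile over candidate cluster numbers
#'
#' @param tree A `cluster_tree`.
#' @param k_range Candidate numbers of clusters (within 2..n_units - 1).
#' @return Named numeric vector, mean silhouette width per K.
#' @export
silhouette_by_k <- function(tree, k_range = 2:10) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (!length(k_range)) stop("empty k_range")
  if (any(k_range < 2 | k_range > tree$n_units - 1))
    stop("k_range must lie within [2, ", tree$n_units - 1, "]")
  vapply(stats::setNames(k_range, k_range), function(k) {
    silhouette_width(tree$dist, stats::cutree(tree$hclust, k))
  }, 0)
}

#' Silhouette-optimal number of clusters
#'
#' @inheritParams silhouette_by_k
#' @return The K in `k_range` maximizing mean silhouette width over the
#'   unit partition; ties resolve to the smallest K.
#' @export
choose_k <- function(tree, k_range = 2:10) {
  sil <- silhouette_by_k(tree, k_range)
  k_range[which.max(sil)]
}

#' Cut the dendrogram and carry subjects through their units
#'
#' @param tree A `cluster_tree`.
#' @param ks Cut levels (each in 1..n_units).
#' @param assignment Subject-to-unit table from [map_subjects()].
#' @return A named list (one element per K) with `unit_clusters` (length
#'   n_units), `subject_clusters` (named by subject id), and `sizes`
#'   (subjects per cluster).
#' @export
cut_partitions <- function(tree, ks = c(2, 11, 27), assignment) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (any(ks < 1 | ks > tree$n_units))
    stop("cut levels must lie in [1, ", tree$n_units, "]")
  out <- lapply(ks, function(k) {
    uc <- if (k == 1) rep(1L, tree$n_units) else
      stats::cutree(tree$hclust, k)
    sc <- stats::setNames(uc[assignment$unit], assignment$id)
    list(unit_clusters = uc, subject_clusters = sc,
         sizes = table(factor(sc, levels = sort(unique(uc)))))
  })
  names(out) <- paste0("K", ks)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected partition agreement from the contingency
#' table of the two labelings.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
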