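## Bootstrap clusterwise Jaccard stability of the full clustering chain.

#' Bootstrap clusterwise Jaccard stability
#'
#' Assesses how reproducible the subject partition at `k` clusters is under
#' resampling.  For each of `n_resamples` bootstrap resamples (subjects
#' drawn with replacement) the whole chain is rerun: feature scaling is
#' refit on the resample, the SOM is retrained (`restarts` restarts), the
#' units are Ward-clustered and cut at `k`.  Each original cluster is then
#' matched to the resample cluster with the largest Jaccard coefficient
#' over the subjects present in both partitions; the coefficient is
#' averaged per cluster over resamples and over clusters for the overall
#' value.  A resample whose dendrogram yields fewer than `k` non-empty
#' subject clusters is skipped and logged.
#'
#' @param cohort Post-exclusion cohort table.
#' @param reference_clusters Named vector (subject id -> cluster) of the
#'   original partition at `k` from the main analysis.
#' @param k Number of clusters.
#' @param grid SOM grid.
#' @param n_resamples Bootstrap resamples (default 100).
#' @param restarts SOM restarts per resample (default 10; the reference
#'   model typically uses more, selection noise here is absorbed by the
#'   stability statistic itself).
#' @param iterations,lr,radius SOM hyperparameters, as in [train_som()].
#' @param seed Master seed; resample draws and SOM restart streams are all
#'   derived from it.
#' @param resample_indices Optional `n_resamples x n` integer matrix of
#'   forced resample indices (testing hook; normally drawn from `seed`).
#' @return An object of class `"stability_report"`: list with
#'   `n_resamples`, `per_cluster` (mean Jaccard per original cluster),
#'   `overall` (unweighted mean over clusters), `jaccard` (resamples x
#'   clusters matrix), `skipped` (indices of skipped resamples).
#' @export
bootstrap_stability <- function(cohort, reference_clusters, k,
                                grid = build_grid(), n_resamples = 100,
                                restarts = 10, iterations = 500,
                                lr = c(0.05, 0.01), radius = NULL, seed = 1,
                                resample_indices = NULL) {
  stopifnot(n_resamples >= 1, k >= 1)
  n <- nrow(cohort)
  clusters <- sort(unique(reference_clusters))
  orig_sets <- lapply(clusters, function(cl)
    names(reference_clusters)[reference_clusters == cl])
  # All resample index draws come from one RNG stream up front, so the
  # per-resample SOM seeds (also derived from `seed`) cannot perturb them.
  set.seed(seed)
  idx_mat <- if (is.null(resample_indices))
    matrix(sample.int(n, n * n_resamples, replace = TRUE),
           nrow = n_resamples)
  else resample_indices
  jac <- matrix(NA_real_, n_resamples, length(clusters),
                dimnames = list(NULL, paste0("cluster_", clusters)))
  skipped <- integer(0)
  for (b in seq_len(n_resamples)) {
    sub <- cohort[idx_mat[b, ], , drop = FALSE]
    feats_b <- scale_features(sub)
    model_b <- restart_best(feats_b, grid, n_restarts = restarts,
                            iterations = iterations, lr = lr, radius = radius,
                            seed = seed + b * 1000L)
    tree_b <- ward_tree(model_b)
    assign_b <- map_subjects(model_b, feats_b)
    part_b <- cut_partitions(tree_b, k, assign_b)[[1]]
    # a subject drawn several times always maps to the same BMU; dedupe
    sc <- part_b$subject_clusters[!duplicated(names(part_b$subject_clusters))]
    if (length(unique(sc)) < k) { skipped <- c(skipped, b); next }
    common <- intersect(unlist(orig_sets), names(sc))
    res_sets <- split(names(sc), sc)
    for (ci in seq_along(clusters)) {
      A <- intersect(orig_sets[[ci]], common)
      if (!length(A)) next
      jac[b, ci] <- max(vapply(res_sets, function(B) {
        Bc <- intersect(B, common)
        length(intersect(A, Bc)) / length(union(A, Bc))
      }, 0))
    }
  }
  per_cluster <- colMeans(jac, na.rm = TRUE)
  structure(
    list(n_resamples = n_resamples, per_cluster = per_cluster,
         overall = mean(per_cluster), jaccard = jac, skipped = skipped,
         k = k),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> K =", x$k, ",", x$n_resamples, "resamples",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"),
      "\n  mean Jaccard per cluster:",
      paste(sprintf("%.3f", x$per_cluster), collapse = ", "),
      "\n  overall:", sprintf("%.3f", x$overall), "\n")
  invisible(x)
}
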