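# Shared fixtures and independent oracles.  Oracles here are deliberately
# naive (double loops, brute-force recomputation) and never call the code
# paths they check.

# A tiny fully-observed cohort with hand-set values, for counting tests.
tiny_cohort <- function(n = 10) {
  cfg <- generator_config(n_subjects = n, missing_rate = 0,
                          medicated_rate = 0, seed = 99)
  generate_cohort(cfg)
}

# feature_layers built directly from a numeric matrix (bypasses cohort
# plumbing for SOM/cluster unit tests).
make_features <- function(x, ids = sprintf("P%03d", seq_len(nrow(x)))) {
  colnames(x) <- clustering_variables()
  structure(
    list(x = x,
         layers = list(glucose = 1:3, cpeptide = 4:6, insulin = 7:9,
                       ffa = 10:12, anthropometric = 13:15),
         scaling = list(), ids = ids,
         sex = rep("female", nrow(x))),
    class = "feature_layers"
  )
}

# A som_model wrapper around a given codebook with unit layer weights,
# for clustering tests that do not need training.
make_model <- function(codebook) {
  colnames(codebook) <- clustering_variables()
  structure(
    list(grid = build_grid(), codebook = codebook,
         layers = list(glucose = 1:3, cpeptide = 4:6, insulin = 7:9,
                       ffa = 10:12, anthropometric = 13:15),
         layer_weights = rep(1, 5), qe = NA_real_),
    class = "som_model"
  )
}

# Brute-force Ward: at every step merge the pair whose union minimizes the
# increase in total within-cluster sum of squares.  Heights relate to
# Ward.D2 by h = sqrt(2 * deltaSSE) (verified numerically).
oracle_ward <- function(X) {
  sse <- function(idx) {
    m <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  cl <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(cl) > 1) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- sse(c(cl[[i]], cl[[j]])) - sse(cl[[i]]) - sse(cl[[j]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(2 * best))
    cl[[bi]] <- c(cl[[bi]], cl[[bj]]); cl[[bj]] <- NULL
    lab <- integer(nrow(X))
    for (k in seq_along(cl)) lab[cl[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Double-loop silhouette with the singleton-scores-zero convention.
oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (k in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == k]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Online k-means with the package's linear learning-rate schedule: the SOM
# update with neighborhood radius forced to 0.
oracle_online_kmeans <- function(x, init, order, lr) {
  M <- init
  total <- length(order)
  denom <- if (total > 1) total - 1 else 1
  for (t in seq_len(total)) {
    xi <- x[order[t], ]
    alpha <- lr[1] + (lr[2] - lr[1]) * (t - 1) / denom
    d <- rowSums(sweep(M, 2, xi)^2)
    b <- which.min(d)
    M[b, ] <- M[b, ] + alpha * (xi - M[b, ])
  }
  M
}

# Two tight, well-separated 27-unit codebook blobs (14 + 13).
two_blob_codebook <- function(seed = 1, gap = 20) {
  set.seed(seed)
  rbind(
    matrix(rnorm(14 * 15, 0, 0.3), 14, 15),
    matrix(rnorm(13 * 15, gap, 0.3), 13, 15)
  )
}
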