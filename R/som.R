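## Multilayer SOM training, restarts, and subject mapping.

.layer_info <- function(features) {
  starts <- vapply(features$layers, function(ix) ix[1] - 1L, 0L)
  lens <- vapply(features$layers, length, 0L)
  list(start = as.integer(starts), len = as.integer(lens))
}

# Per-layer distance normalization: each layer's squared distances are
# divided by the data-wide mean squared distance of samples to the layer
# mean (= the sum of the layer's column variances), so all layers
# contribute comparably to the BMU criterion.
.layer_weights <- function(x, layers) {
  w <- vapply(layers, function(ix) {
    v <- sum(apply(x[, ix, drop = FALSE], 2, stats::var))
    if (!is.finite(v) || v <= 0)
      stop("degenerate layer (zero variance); cannot normalize")
    1 / v
  }, 0)
  w
}

#' Train a multilayer self-organizing map
#'
#' Sequential (one sample at a time) training on the five feature layers
#' with a shared toroidal hexagonal grid.  The best-matching unit minimizes
#' the layer-normalized weighted squared Euclidean distance
#' `sum_l w_l ||x_l - m_l||^2`; the update moves every layer of every unit
#' within the Gaussian neighborhood of the BMU by
#' `alpha(t) h(u, bmu; sigma(t)) (x - m)`.  The learning rate decreases
#' linearly from `lr[1]` to `lr[2]`; the neighborhood radius decreases
#' linearly from `radius` (default: the 67th percentile of the inter-unit
#' grid distances, i.e. "two thirds of the units") to 0 at the final step.
#' One iteration is one pass over the data in randomized order.  Codebooks
#' are initialized by sampling `n_units` distinct subjects.  The run is
#' fully determined by `seed`.
#'
#' @param features A `feature_layers` object (see [scale_features()]).
#' @param grid A `som_grid` (default 3 x 9).
#' @param iterations Passes over the data (default 500).
#' @param lr Length-2 learning-rate schedule, default `c(0.05, 0.01)`.
#' @param radius Initial neighborhood radius; `NULL` for the default.
#'   `0` degenerates to online k-means (only the BMU moves).
#' @param seed Integer seed (required unless both `init` and `order` are
#'   supplied).
#' @param init Optional initial codebook matrix (`n_units x 15`).
#' @param order Optional `iterations x n` integer matrix of 1-based
#'   presentation orders (testing hook; normally generated from `seed`).
#' @return An object of class `"som_model"`: list with `grid`, `codebook`
#'   (`n_units x 15`), `layers`, `layer_weights`, `qe` (quantization
#'   error: mean distance of subjects to their BMU), `iterations`, `lr`,
#'   `radius_start`, `seed`.
#' @export
train_som <- function(features, grid = build_grid(), iterations = 500,
                      lr = c(0.05, 0.01), radius = NULL, seed = NULL,
                      init = NULL, order = NULL) {
  stopifnot(inherits(features, "feature_layers"), inherits(grid, "som_grid"))
  x <- features$x
  n <- nrow(x)
  if (anyNA(x)) stop("features contain missing values")
  if (is.null(init) && n < grid$n_units)
    stop("need at least as many subjects (", n, ") as units (",
         grid$n_units, ") to initialize codebooks")
  if (!is.null(seed)) set.seed(seed)
  else if (is.null(init) || is.null(order))
    stop("seed is required unless init and order are both supplied")
  if (is.null(init))
    init <- x[sample.int(n, grid$n_units), , drop = FALSE]
  if (is.null(order)) {
    if (iterations > 0)
      order <- t(vapply(seq_len(iterations), function(e) sample.int(n),
                        integer(n)))
    else
      order <- matrix(integer(0), 0, n)
  }
  if (is.null(radius))
    radius <- as.numeric(stats::quantile(grid$dist[upper.tri(grid$dist)], 2 / 3))
  w <- .layer_weights(x, features$layers)
  li <- .layer_info(features)
  codebook <- if (nrow(order) == 0) init else
    t(.som_train_cpp(t(x), t(init), li$start, li$len, w, grid$dist2,
                     order - 1L, lr[1], lr[2], radius))
  colnames(codebook) <- colnames(x)
  mapped <- .som_map_cpp(t(x), t(codebook), li$start, li$len, w)
  structure(
    list(grid = grid, codebook = codebook, layers = features$layers,
         layer_weights = w, qe = mean(mapped$dist),
         iterations = iterations, lr = lr, radius_start = radius,
         seed = seed),
    class = "som_model"
  )
}

#' Train with random restarts, keep the lowest quantization error
#'
#' Runs [train_som()] `n_restarts` times with seeds `seed, seed + 1, ...`
#' (a deterministic stream, so a larger restart budget always contains the
#' smaller one) and returns the model with the lowest quantization error;
#' ties go to the earliest seed.
#'
#' @inheritParams train_som
#' @param n_restarts Number of restarts (>= 1).
#' @param seed Master seed for the restart stream.
#' @return The best `som_model`, with an extra element `restart_log`
#'   (data.frame of seed and qe per restart).
#' @export
restart_best <- function(features, grid = build_grid(), n_restarts = 100,
                         iterations = 500, lr = c(0.05, 0.01),
                         radius = NULL, seed = 1) {
  stopifnot(n_restarts >= 1)
  best <- NULL
  qes <- numeric(n_restarts)
  seeds <- seed + seq_len(n_restarts) - 1L
  for (r in seq_len(n_restarts)) {
    m <- train_som(features, grid, iterations = iterations, lr = lr,
                   radius = radius, seed = seeds[r])
    qes[r] <- m$qe
    if (is.null(best) || m$qe < best$qe) best <- m
  }
  best$restart_log <- data.frame(seed = seeds, qe = qes)
  best
}

#' Map subjects to their best-matching units
#'
#' @param model A `som_model`.
#' @param features A `feature_layers` object with the same 15 columns the
#'   model was trained on.
#' @return data.frame with columns `id`, `unit` (1-based BMU index) and
#'   `dist` (layer-weighted distance to the BMU).
#' @export
map_subjects <- function(model, features) {
  stopifnot(inherits(model, "som_model"), inherits(features, "feature_layers"))
  if (ncol(features$x) != ncol(model$codebook))
    stop("feature dimensionality (", ncol(features$x),
         ") does not match codebooks (", ncol(model$codebook), ")")
  li <- .layer_info(features)
  mapped <- .som_map_cpp(t(features$x), t(model$codebook), li$start, li$len,
                         model$layer_weights)
  data.frame(id = features$ids, unit = mapped$unit, dist = mapped$dist,
             stringsAsFactors = FALSE)
}

#' Recompute the quantization error of a model on given data
#' @param model A `som_model`.
#' @param features A `feature_layers` object.
#' @return Mean distance of subjects to their BMU.
#' @export
quantization_error <- function(model, features) {
  mean(map_subjects(model, features)$dist)
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model>", x$grid$n_units, "units,",
      length(x$layers), "layers, qe =", format(x$qe, digits = 6), "\n")
  invisible(x)
}
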