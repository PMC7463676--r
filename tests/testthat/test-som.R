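test_that("toroidal hexagonal grid geometry", {
  g <- build_grid(3, 9)
  expect_equal(g$n_units, 27)
  expect_equal(diag(g$dist), rep(0, 27))
  expect_equal(g$dist, t(g$dist))

  # toroidal distances never exceed planar ones
  planar <- as.matrix(stats::dist(g$coords))
  expect_true(all(g$dist <= planar + 1e-12))

  # brute-force neighbor counts on the wrapped lattice: middle-row units
  # have the full 6 neighbors at distance 1; the odd-row-count seam gives
  # each outer-row unit 4 neighbors at 1 plus its vertical wrap partner at
  # sqrt(3)/2 (the seam irregularity of a 3-row hexagonal torus)
  nb1 <- apply(g$dist, 1, function(d) sum(abs(d - 1) < 1e-9))
  nbseam <- apply(g$dist, 1, function(d) sum(abs(d - sqrt(3) / 2) < 1e-9))
  middle <- 10:18  # row-major: units of row 2 of 3
  expect_true(all(nb1[middle] == 6))
  expect_true(all(nbseam[middle] == 0))
  expect_true(all(nb1[-middle] == 4))
  expect_true(all(nbseam[-middle] == 1))

  expect_error(build_grid(0, 9), "positive")
})

test_that("training is deterministic, order-sensitive, init-preserving", {
  set.seed(1)
  f <- make_features(matrix(rnorm(60 * 15), 60, 15))
  m1 <- train_som(f, iterations = 30, seed = 11)
  m2 <- train_som(f, iterations = 30, seed = 11)
  expect_identical(m1$codebook, m2$codebook)
  m3 <- train_som(f, iterations = 30, seed = 12)
  expect_false(identical(m1$codebook, m3$codebook))

  # zero iterations: codebooks equal the initialization
  init <- f$x[1:27, ]
  m0 <- train_som(f, iterations = 0, seed = 1, init = init)
  expect_equal(m0$codebook, init, ignore_attr = TRUE)

  # permuting the presentation order changes the fit
  ord <- t(vapply(1:30, function(e) sample.int(60), integer(60)))
  ma <- train_som(f, iterations = 30, seed = 1, init = init, order = ord)
  mb <- train_som(f, iterations = 30, seed = 1, init = init,
                  order = ord[, 60:1])
  expect_false(identical(ma$codebook, mb$codebook))
  expect_error(train_som(make_features(matrix(rnorm(150), 10, 15)),
                         seed = 1), "at least as many subjects")
})

test_that("27 well-separated points each claim a distinct unit, qe -> 0", {
  set.seed(2)
  centers <- matrix(rnorm(27 * 15, sd = 30), 27, 15)
  f <- make_features(centers)
  # with the neighborhood radius below the lattice spacing the map is a
  # pure vector quantizer and must place one unit on each point; a wide
  # initial radius can topologically trap units (random points have no
  # toroidal arrangement), so only the quantization error is asserted there
  m <- train_som(f, iterations = 500, radius = 0.5, seed = 3)
  a <- map_subjects(m, f)
  expect_equal(length(unique(a$unit)), 27)
  expect_lt(m$qe, 1e-2)
  mdef <- train_som(f, iterations = 500, seed = 3)
  expect_lt(mdef$qe, 0.05 * mean(sqrt(rowSums(centers^2))))
})

test_that("quantization error bookkeeping and restart nesting", {
  set.seed(3)
  f <- make_features(matrix(rnorm(80 * 15), 80, 15))
  b10 <- restart_best(f, n_restarts = 10, iterations = 20, seed = 7)
  expect_equal(b10$qe, min(b10$restart_log$qe))
  expect_equal(quantization_error(b10, f), b10$qe, tolerance = 1e-12)
  b25 <- restart_best(f, n_restarts = 25, iterations = 20, seed = 7)
  expect_lte(b25$qe, b10$qe)
  b1 <- restart_best(f, n_restarts = 1, iterations = 20, seed = 7)
  single <- train_som(f, iterations = 20, seed = 7)
  expect_identical(b1$codebook, single$codebook)
})

test_that("subject mapping: exact hits, duplication, conservation", {
  set.seed(4)
  f <- make_features(matrix(rnorm(50 * 15), 50, 15))
  m <- train_som(f, iterations = 50, seed = 5)
  # a subject placed exactly on a codebook vector maps there at distance 0
  probe <- make_features(m$codebook[c(4, 19), ], ids = c("a", "b"))
  pm <- map_subjects(m, probe)
  expect_equal(pm$unit, c(4, 19))
  expect_equal(pm$dist, c(0, 0), tolerance = 1e-12)
  # duplicating a subject leaves assignments unchanged
  dup <- make_features(rbind(f$x, f$x[1, ]),
                       ids = c(f$ids, "dup"))
  ad <- map_subjects(m, dup)
  expect_equal(ad$unit[51], ad$unit[1])
  # occupancies sum to n
  a <- map_subjects(m, f)
  expect_equal(sum(table(a$unit)), 50)
  bad <- f; bad$x <- bad$x[, 1:10]; bad$layers <- list(g = 1:5, h = 6:10)
  expect_error(map_subjects(m, bad), "dimensionality")
})

test_that("radius 0 reduces to online k-means (independent oracle)", {
  set.seed(6)
  x <- matrix(rnorm(40 * 15), 40, 15)
  f <- make_features(x)
  init <- x[1:27, ]
  ord <- t(vapply(1:10, function(e) sample.int(40), integer(40)))
  m <- train_som(f, iterations = 10, radius = 0, init = init, order = ord,
                 seed = 1)
  # the layer weights scale distances, not updates: with radius 0 only the
  # BMU moves, and the weighted-metric BMU equals the plain-Euclidean BMU
  # of the column-scaled data, so the oracle runs on sqrt(w)-scaled inputs
  # and its result is unscaled for comparison
  w <- rep(sqrt(metafoot:::.layer_weights(x, f$layers)), each = 3)
  Mo <- oracle_online_kmeans(sweep(x, 2, w, "*"), sweep(init, 2, w, "*"),
                             as.vector(t(ord)), c(0.05, 0.01))
  expect_equal(sweep(m$codebook, 2, w, "*"), Mo, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("relabeling the grid yields the permuted model", {
  set.seed(7)
  x <- matrix(rnorm(40 * 15), 40, 15)
  f <- make_features(x)
  init <- x[1:27, ]
  ord <- t(vapply(1:10, function(e) sample.int(40), integer(40)))
  g <- build_grid()
  m <- train_som(f, g, iterations = 10, init = init, order = ord, seed = 1)
  # translating every unit by 3 columns is a toroidal symmetry: unit
  # (r, c) -> (r, (c + 3) mod 9), row-major indices
  r <- rep(0:2, each = 9); cc <- rep(0:8, times = 3)
  perm <- r * 9 + ((cc + 3) %% 9) + 1
  expect_lt(max(abs(g$dist[perm, perm] - g$dist)), 1e-12)
  # so initializing unit k with what unit perm[k] had reproduces the
  # original model up to that relabeling
  m3 <- train_som(f, g, iterations = 10, init = init[perm, ], order = ord,
                  seed = 1)
  expect_equal(m3$codebook, m$codebook[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sort(map_subjects(m3, f)$dist),
               sort(map_subjects(m, f)$dist), tolerance = 1e-12)
})
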