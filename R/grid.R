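## Toroidal hexagonal SOM grid.

#' Build a toroidal hexagonal SOM grid
#'
#' Units are laid out row-major on a `rows x cols` hexagonal lattice with
#' offset rows: unit (r, c) sits at `x = c + (r mod 2)/2`,
#' `y = r * sqrt(3)/2` (r, c zero-based).  The grid is toroidal: the
#' inter-unit distance is the minimum Euclidean distance over the nine
#' wrap translations of one lattice in x (period `cols`) and y (period
#' `rows * sqrt(3)/2`).  With an odd number of rows the vertical wrap
#' joins two rows of equal offset parity, so the seam row pairs sit at
#' distance `sqrt(3)/2` instead of 1 - a documented irregularity of any
#' hexagonal torus whose dimensions are not both even (27 units admits
#' none).
#'
#' @param rows,cols Grid dimensions (default 3 x 9 = 27 units).
#' @return An object of class `"som_grid"`: list with `rows`, `cols`,
#'   `n_units`, `coords` (n_units x 2), `dist` (toroidal distance matrix)
#'   and `dist2` (its square).
#' @export
build_grid <- function(rows = 3, cols = 9) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive")
  rows <- as.integer(rows); cols <- as.integer(cols)
  r <- rep(seq_len(rows) - 1L, each = cols)
  cc <- rep(seq_len(cols) - 1L, times = rows)
  xy <- cbind(x = cc + (r %% 2) / 2, y = r * sqrt(3) / 2)
  px <- cols
  py <- rows * sqrt(3) / 2
  n <- rows * cols
  d2 <- matrix(Inf, n, n)
  for (sx in -1:1) for (sy in -1:1) {
    dx <- outer(xy[, 1], xy[, 1] + sx * px, "-")
    dy <- outer(xy[, 2], xy[, 2] + sy * py, "-")
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  structure(
    list(rows = rows, cols = cols, n_units = n, coords = xy,
         dist = sqrt(d2), dist2 = d2),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid>", x$rows, "x", x$cols, "toroidal hexagonal,",
      x$n_units, "units\n")
  invisible(x)
}
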