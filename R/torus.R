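#' Torus geometry helpers
#'
#' All spatial dynamics in this package live on the unit torus, the square
#' `[0,1)^2` with periodic boundaries in both coordinates. These helpers wrap
#' coordinates, compute minimum-image displacements and periodic distances.
#'
#' @param x numeric vector/matrix of coordinates.
#' @return `wrap_torus()` returns coordinates wrapped to `[0,1)`.
#' @examples
#' wrap_torus(c(1.2, -0.1))
#' torus_delta(0.95, 0.05)   # +0.10, the short way round
#' @export
wrap_torus <- function(x) {
  x - floor(x)
}

#' @rdname wrap_torus
#' @param from,to coordinates (vectors or matrices with matching shape).
#' @return `torus_delta()` returns the minimum-image displacement `to - from`,
#'   each component in `(-0.5, 0.5]`.
#' @export
torus_delta <- function(from, to) {
  d <- to - from
  d - round(d)
}

#' @rdname wrap_torus
#' @param x1,y1,x2,y2 coordinate component vectors.
#' @return `torus_dist()` returns the periodic Euclidean distance.
#' @export
torus_dist <- function(x1, y1, x2, y2) {
  dx <- torus_delta(x1, x2)
  dy <- torus_delta(y1, y2)
  sqrt(dx * dx + dy * dy)
}

#' Periodic bilinear interpolation on a square grid
#'
#' Interprets `grid[i, j]` as the value at the cell-centre-free lattice point
#' `x = (i-1)/n`, `y = (j-1)/n`, and interpolates bilinearly with periodic
#' wraparound. Used both for sampling the resource concentration at agent
#' positions and for off-grid velocity lookups in the semi-Lagrangian
#' advection step.
#'
#' @param grid an `n x n` numeric matrix of nodal values.
#' @param px,py query coordinates (any real values; wrapped internally).
#' @return numeric vector of interpolated values.
#' @keywords internal
interp_bilinear <- function(grid, px, py) {
  n <- nrow(grid)
  gx <- wrap_torus(px) * n
  gy <- wrap_torus(py) * n
  i0 <- floor(gx)
  j0 <- floor(gy)
  fx <- gx - i0
  fy <- gy - j0
  i0 <- i0 %% n
  j0 <- j0 %% n
  i1 <- (i0 + 1L) %% n
  j1 <- (j0 + 1L) %% n
  # convert to 1-based linear indices into the matrix
  v00 <- grid[1L + i0 + n * j0]
  v10 <- grid[1L + i1 + n * j0]
  v01 <- grid[1L + i0 + n * j1]
  v11 <- grid[1L + i1 + n * j1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}
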