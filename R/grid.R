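#' Regular Cartesian grid over a circular plate
#'
#' Builds an `nx x ny` lattice of square cells of edge `h` (cm) covering
#' the plate bounding box, with the origin at the plate centre. Cell
#' `(i, j)` has its centre at `((i - 1/2) h - extent/2, (j - 1/2) h -
#' extent/2)`. The boolean `mask` marks cells whose centre lies inside the
#' plate radius; fields are defined (and conserved) only on the mask, and
#' all face fluxes across the mask boundary are zero.
#'
#' @param h cell edge length, cm.
#' @param R_plate plate radius, cm.
#' @return object of class `plate_grid`: list with `h`, `nx`, `ny`, `x`,
#'   `y` (cell-centre coordinate vectors), `xc`, `yc` (coordinate
#'   matrices), `r` (radius matrix), `mask`, `R_plate`.
#' @export
plate_grid <- function(h, R_plate = 5.5) {
  stopifnot(is.numeric(h), length(h) == 1L, h > 0, R_plate > h)
  n <- as.integer(ceiling(2 * R_plate / h))
  extent <- n * h
  x <- (seq_len(n) - 0.5) * h - extent / 2
  xc <- matrix(x, n, n)
  yc <- matrix(x, n, n, byrow = TRUE)
  r <- sqrt(xc^2 + yc^2)
  g <- list(h = h, nx = n, ny = n, x = x, y = x, xc = xc, yc = yc,
            r = r, mask = r <= R_plate, R_plate = R_plate)
  class(g) <- "plate_grid"
  g
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("<plate_grid> %d x %d cells, h = %g cm, plate R = %g cm (%d cells in mask)\n",
              x$nx, x$ny, x$h, x$R_plate, sum(x$mask)))
  invisible(x)
}

#' Index of the grid cell nearest a point
#'
#' @param grid a [plate_grid()].
#' @param x,y coordinates (cm) relative to the plate centre.
#' @return integer vector `c(i, j)` (1-based).
#' @export
grid_cell_at <- function(grid, x, y) {
  i <- which.min(abs(grid$x - x))
  j <- which.min(abs(grid$y - y))
  c(i, j)
}

#' Snapshot of the four model fields
#'
#' @param t time (h).
#' @param B,L,P,n density matrices (um^-2) of shape `nx x ny`; values must
#'   be finite, nonnegative on the mask and zero outside it.
#' @param grid the [plate_grid()] the fields live on.
#' @return object of class `field_state`.
#' @export
field_state <- function(t, B, L, P, n, grid) {
  for (nm in c("B", "L", "P", "n")) {
    v <- get(nm)
    if (!is.matrix(v) || !all(dim(v) == c(grid$nx, grid$ny)))
      stop(sprintf("field '%s' must be a %d x %d matrix", nm,
                   grid$nx, grid$ny), call. = FALSE)
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("field '%s' must be finite and nonnegative", nm),
           call. = FALSE)
    if (any(v[!grid$mask] != 0))
      stop(sprintf("field '%s' must vanish outside the plate mask", nm),
           call. = FALSE)
  }
  s <- list(t = t, B = B, L = L, P = P, n = n, grid = grid)
  class(s) <- "field_state"
  s
}

#' @export
print.field_state <- function(x, ...) {
  h2 <- x$grid$h^2
  cat(sprintf("<field_state> t = %.4g h | totals (counts x 1e8): B %.4g L %.4g P %.4g n %.4g\n",
              x$t, sum(x$B) * h2, sum(x$L) * h2, sum(x$P) * h2, sum(x$n) * h2))
  invisible(x)
}

#' Total particle/cell counts in a field state
#'
#' Integrates each density over the plate. Densities are carried in
#' um^-2 on a cm grid, so the cell area `h^2` cm^2 corresponds to
#' `h^2 * 1e8` um^2.
#'
#' @param s a [field_state()].
#' @return named numeric vector of counts for B, L, P and n.
#' @export
field_totals <- function(s) {
  a <- s$grid$h^2 * UM2_PER_CM2
  c(B = sum(s$B) * a, L = sum(s$L) * a, P = sum(s$P) * a, n = sum(s$n) * a)
}
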