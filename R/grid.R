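#' Build a uniform square-cell grid
#'
#' The computational domain is a rectangle (default `[0,5] x [0,5]`)
#' discretized into `nx x ny` interior nodes at positions
#' `(x0 + i*h, y0 + j*h)`, `i = 1..nx`, so the mesh size follows the
#' convention `h = L/(nx+1)` with `L` the domain width. The boundary ring is
#' not stored: zero-flux (Neumann) closure is applied by mirrored ghost
#' values inside the discrete operators.
#'
#' @param nx,ny number of interior nodes per axis (`ny` defaults to `nx`).
#' @param extent domain rectangle as `c(x0, x1, y0, y1)`.
#' @return An object of class `pf_grid`: list with `nx`, `ny`, `h`, node
#'   coordinates `x`, `y`, and `extent`.
#' @examples
#' g <- build_grid(99)        # h = 5/100 = 0.05
#' g$h
#' @export
build_grid <- function(nx, ny = nx, extent = c(0, 5, 0, 5)) {
  stopifnot(length(extent) == 4, nx >= 3, ny >= 3,
            nx == as.integer(nx), ny == as.integer(ny))
  Lx <- extent[2] - extent[1]
  Ly <- extent[4] - extent[3]
  if (Lx <= 0 || Ly <= 0) stop("degenerate extent")
  hx <- Lx / (nx + 1)
  hy <- Ly / (ny + 1)
  if (abs(hx - hy) > 1e-12 * hx)
    stop("grid cells must be square: got hx = ", hx, ", hy = ", hy)
  g <- list(nx = as.integer(nx), ny = as.integer(ny), h = hx,
            x = extent[1] + seq_len(nx) * hx,
            y = extent[3] + seq_len(ny) * hy,
            extent = extent)
  class(g) <- "pf_grid"
  g
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("<pf_grid> %d x %d interior nodes, h = %g, extent [%g,%g] x [%g,%g]\n",
              x$nx, x$ny, x$h, x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

#' Evaluate a function of (x, y) on all grid nodes
#'
#' @param grid a [build_grid()] grid.
#' @param f vectorized function of two coordinate arguments.
#' @return `nx x ny` matrix (rows index x, columns index y).
#' @export
eval_on_grid <- function(grid, f) {
  outer(grid$x, grid$y, f)
}

check_field <- function(f, grid) {
  if (!is.matrix(f) || nrow(f) != grid$nx || ncol(f) != grid$ny)
    stop("field is not a ", grid$nx, " x ", grid$ny, " matrix")
  if (!all(is.finite(f))) stop("field contains non-finite values")
  invisible(f)
}

#' Five-point Laplacian with zero-flux closure
#'
#' Second-order stencil; boundary closed by mirrored ghosts so that
#' `sum(laplacian(f)) * h^2 == 0` exactly (discrete divergence theorem).
#'
#' @param f field matrix.
#' @param grid the grid `f` lives on.
#' @export
laplacian <- function(f, grid) {
  check_field(f, grid)
  cpp_laplacian(f, grid$h)
}

#' Central-difference gradient with mirrored boundary closure
#'
#' Interior nodes use central differences; at the boundary the mirrored ghost
#' makes the one-sided formula `(f[2]-f[1])/(2h)`, consistent with the
#' Neumann closure used by [laplacian()].
#'
#' @inheritParams laplacian
#' @return list with components `x` and `y` (matrices).
#' @export
gradient <- function(f, grid) {
  check_field(f, grid)
  list(x = cpp_gradx(f, grid$h), y = cpp_grady(f, grid$h))
}

#' Rotate a vector field by +90 degrees
#'
#' `(vx, vy) -> (-vy, vx)`. Used to turn the cluster-boundary normal
#' `grad(phi_c)` into the interface tangent. The TIM force is invariant to
#' the choice of rotation sense (the sign factor flips with it).
#'
#' @param v list with matrices `x`, `y`.
#' @export
perp <- function(v) {
  list(x = -v$y, y = v$x)
}

#' Smooth indicator interpolation h(phi) = phi^2 (3 - 2 phi)
#'
#' Maps 0 -> 0 and 1 -> 1 with zero derivative at both, approximating the
#' characteristic function of the cell domain; used for volumes and all
#' inter-cell couplings. Outside the unit interval the cubic is clamped to
#' its end values (the C1 smoothstep): the raw cubic is non-monotone there,
#' which would make the overlap energy unbounded below under transient
#' overshoots of the explicit scheme.
#'
#' @param phi numeric vector/matrix of phase values.
#' @export
interp_h <- function(phi) {
  p <- pmin(pmax(phi, 0), 1)
  p * p * (3 - 2 * p)
}

#' Derivative of the indicator interpolation
#'
#' `h'(phi) = 6 phi (1 - phi)` on the unit interval, zero outside it
#' (matching the clamped [interp_h()] exactly).
#' @inheritParams interp_h
#' @export
interp_h_prime <- function(phi) {
  ifelse(phi <= 0 | phi >= 1, 0, 6 * phi * (1 - phi))
}

#' Cell volume (area) of a phase field
#'
#' Midpoint quadrature of the smooth indicator: `sum(interp_h(phi)) * h^2`.
#'
#' @inheritParams laplacian
#' @export
volume <- function(f, grid) {
  sum(interp_h(f)) * grid$h^2
}

#' Equilibrium diffuse-interface profile of a disc
#'
#' A tanh disc: `phi = 1/2 (1 - tanh(d / (2 sqrt(2) eps)))` with `d` the
#' signed distance to the circle of radius `r` (positive outside). This is
#' the 1D equilibrium profile of the double-well plus square-gradient
#' energy, so initial cells start close to their relaxed interface shape.
#'
#' @param grid grid.
#' @param center length-2 numeric, disc center.
#' @param r radius.
#' @param eps2 interface-width parameter (the profile scale is `sqrt(eps2)`).
#' @export
tanh_disc <- function(grid, center, r, eps2) {
  eps <- sqrt(eps2)
  eval_on_grid(grid, function(x, y) {
    d <- sqrt((x - center[1])^2 + (y - center[2])^2) - r
    0.5 * (1 - tanh(d / (2 * sqrt(2) * eps)))
  })
}
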