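PF_TYPES <- c("nurse", "cluster", "oocyte")

#' Per-cell phase-field parameters
#'
#' @param type one of `"nurse"`, `"cluster"`, `"oocyte"`.
#' @param eps2 squared interface-width parameter. Defaults: 0.001 for nurse
#'   cells and the oocyte, 0.0005 for the border cell cluster (its interface
#'   is sharper so the small cluster stays compact).
#' @param alpha volume-penalty stiffness (default 100 for every cell).
#' @param Vbar target volume in model units.
#' @return list of class `pf_cell_params`.
#' @export
cell_params <- function(type, Vbar,
                        eps2 = if (type == "cluster") 5e-4 else 1e-3,
                        alpha = 100) {
  type <- match.arg(type, PF_TYPES)
  stopifnot(eps2 > 0, alpha >= 0, Vbar >= 0)
  structure(list(type = type, eps2 = eps2, alpha = alpha, Vbar = Vbar),
            class = "pf_cell_params")
}

#' Type-pair interaction tables
#'
#' Symmetric 3 x 3 matrices indexed by cell type (nurse, cluster, oocyte)
#' holding the exclusion intensities `beta` (overlap penalty) and adhesion
#' intensities `gamma` (gradient coupling), plus the epithelium couplings
#' `beta0`, `gamma0` and the global chamber-filling stiffness `alpha0`.
#' Diagonal entries for the singleton types (cluster, oocyte) are zero.
#'
#' The double sums in the pairwise energies count each unordered pair twice;
#' the tabulated intensities are defined under that convention.
#'
#' The default adhesion intensities keep the relative strengths
#' nurse-nurse : nurse-cluster : cluster-oocyte : nurse-oocyte =
#' 3 : 4 : 5 : 8 at a magnitude inside the linear-stability bound of the
#' gradient flow: the adhesion force on cell `m` carries `gamma * lap h(phi_n)`,
#' and `|lap h|` at a resolved interface is of order `0.1/eps2`, so
#' `gamma` beyond a few times `1e-4` makes `phi = 0` unstable next to a
#' partner interface (partner fields nucleate there and the interfaces foam).
#' See the methods vignette for the derivation.
#'
#' @param beta0 epithelium-cell exclusion intensity.
#' @param beta 3 x 3 symmetric exclusion matrix (dimnames = cell types).
#' @param gamma0 epithelium-cell adhesion intensity.
#' @param gamma 3 x 3 symmetric adhesion matrix.
#' @param alpha0 global interior-filling stiffness.
#' @param barrier stiffness of the C1 containment well outside the unit
#'   interval (zero on `[0,1]`). With the indicator clamped, only the weak
#'   double well restores phase overshoots; the barrier bounds the
#'   excursions that strong guidance forces can drive.
#' @export
interaction_tables <- function(beta0 = 0.9,
                               beta = default_beta(),
                               gamma0 = 1e-4,
                               gamma = default_gamma(),
                               alpha0 = 0.02,
                               barrier = 300) {
  beta <- as_type_matrix(beta, "beta")
  gamma <- as_type_matrix(gamma, "gamma")
  if (!isTRUE(all.equal(beta, t(beta))) || !isTRUE(all.equal(gamma, t(gamma))))
    stop("interaction matrices must be symmetric")
  stopifnot(barrier >= 0)
  structure(list(beta0 = beta0, beta = beta, gamma0 = gamma0, gamma = gamma,
                 alpha0 = alpha0, barrier = barrier),
            class = "pf_tables")
}

default_beta <- function() {
  m <- matrix(0, 3, 3, dimnames = list(PF_TYPES, PF_TYPES))
  m["nurse", "nurse"] <- 0.25
  m["nurse", "cluster"] <- m["cluster", "nurse"] <- 0.25
  m["nurse", "oocyte"] <- m["oocyte", "nurse"] <- 0.25
  m["cluster", "oocyte"] <- m["oocyte", "cluster"] <- 0.3
  m
}

default_gamma <- function() {
  m <- matrix(0, 3, 3, dimnames = list(PF_TYPES, PF_TYPES))
  m["nurse", "nurse"] <- 6e-5
  m["nurse", "cluster"] <- m["cluster", "nurse"] <- 8e-5
  m["nurse", "oocyte"] <- m["oocyte", "nurse"] <- 1.6e-4
  m["cluster", "oocyte"] <- m["oocyte", "cluster"] <- 1e-4
  m
}

as_type_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(3L, 3L)))
    stop(what, " must be a 3 x 3 type-pair matrix")
  if (is.null(dimnames(m))) dimnames(m) <- list(PF_TYPES, PF_TYPES)
  m[PF_TYPES, PF_TYPES]
}

#' Assemble a phase-field system state
#'
#' Bundles the grid, the static epithelium field `phi0` (0 inside the
#' chamber, 1 outside), the stack of dynamic cell fields, their per-cell
#' parameters, and the interaction tables.
#'
#' @param grid a [build_grid()] grid.
#' @param phi0 epithelium matrix.
#' @param phi `nx x ny x N` array of dynamic fields, or a list of matrices.
#' @param params list of N [cell_params()] entries (one per dynamic field).
#' @param tables an [interaction_tables()] object.
#' @param time current simulation time.
#' @return object of class `pf_state`.
#' @export
pf_state <- function(grid, phi0, phi, params, tables = interaction_tables(),
                     time = 0) {
  if (is.list(phi)) phi <- simplify2array(phi)
  stopifnot(length(dim(phi)) == 3)
  N <- dim(phi)[3]
  if (length(params) != N) stop("need one cell_params entry per dynamic field")
  check_field(phi0, grid)
  types <- vapply(params, `[[`, "", "type")
  if (sum(types == "cluster") != 1)
    stop("state must contain exactly one cluster")
  if (sum(types == "oocyte") > 1)
    stop("state may contain at most one oocyte")
  s <- list(grid = grid, phi0 = phi0, phi = phi, params = params,
            tables = tables, time = time,
            cluster = which(types == "cluster"),
            oocyte = if (any(types == "oocyte")) which(types == "oocyte") else NA_integer_,
            nurse = which(types == "nurse"))
  class(s) <- "pf_state"
  s
}

#' @export
print.pf_state <- function(x, ...) {
  v <- cell_volumes(x)
  cat(sprintf("<pf_state> t = %g, %d dynamic cells on %d x %d grid\n",
              x$time, length(x$params), x$grid$nx, x$grid$ny))
  for (m in seq_along(x$params)) {
    p <- x$params[[m]]
    cat(sprintf("  [%d] %-8s V = %.3f (target %.3f)\n", m, p$type, v[m], p$Vbar))
  }
  invisible(x)
}

#' Current volumes of all dynamic cells
#' @param state a [pf_state()].
#' @export
cell_volumes <- function(state) {
  vapply(seq_len(dim(state$phi)[3]),
         function(m) volume(state$phi[, , m], state$grid), 0)
}

#' Interior area of the chamber, integral of (1 - h(phi0))
#' @param state a [pf_state()].
#' @export
interior_area <- function(state) {
  sum(1 - interp_h(state$phi0)) * state$grid$h^2
}

# Expand typed tables + per-cell params into the flat parameter list the
# compiled core consumes (per-cell N x N matrices, vectors per cell).
pars_for_cpp <- function(state, mu = 1) {
  types <- vapply(state$params, `[[`, "", "type")
  N <- length(types)
  beta <- state$tables$beta[types, types, drop = FALSE]
  gamma <- state$tables$gamma[types, types, drop = FALSE]
  diag(beta) <- 0
  diag(gamma) <- 0
  list(h = state$grid$h, mu = mu,
       beta0 = state$tables$beta0, gamma0 = state$tables$gamma0,
       alpha0 = state$tables$alpha0,
       barrier = if (is.null(state$tables$barrier)) 300 else state$tables$barrier,
       eps2 = vapply(state$params, `[[`, 0, "eps2"),
       alpha = vapply(state$params, `[[`, 0, "alpha"),
       Vbar = vapply(state$params, `[[`, 0, "Vbar"),
       beta = unname(beta), gamma = unname(gamma))
}
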