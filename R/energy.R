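# Free energy of the multicellular system and its gradient-flow RHS.
#
# All gradient-square integrals are discretized with *face* (forward)
# differences over interior faces, with zero flux across the boundary. Under
# that quadrature the 5-point mirrored-ghost Laplacian used in the evolution
# equation is the exact derivative of the discrete energy with respect to
# each nodal value, so descent holds at the discrete level.

face_dot_r <- function(f, g, h) {
  (sum((f[-1, ] - f[-nrow(f), ]) * (g[-1, ] - g[-nrow(g), ])) +
     sum((f[, -1] - f[, -ncol(f)]) * (g[, -1] - g[, -ncol(g)]))) / h^2
}

dwell_g <- function(phi) 0.25 * (phi * (1 - phi))^2

contain_g <- function(phi, B) {
  0.5 * B * (pmin(phi, 0)^2 + pmax(phi - 1, 0)^2)
}

#' Bulk + interface + volume-penalty energy (per-cell term)
#'
#' Sum over dynamic cells of the square-gradient interface energy, the
#' double-well potential `g(phi) = phi^2 (1-phi)^2 / 4` (augmented by the
#' containment well outside the unit interval, see [interaction_tables()]),
#' and the volume penalty `alpha_m (V_m - Vbar_m)^2`.
#'
#' @param state a [pf_state()].
#' @export
energy_E0 <- function(state) {
  g <- state$grid
  h2 <- g$h^2
  B <- if (is.null(state$tables$barrier)) 300 else state$tables$barrier
  tot <- 0
  for (m in seq_along(state$params)) {
    p <- state$params[[m]]
    phi <- state$phi[, , m]
    tot <- tot + 0.5 * p$eps2 * face_dot_r(phi, phi, g$h) * h2 +
      sum(dwell_g(phi) + contain_g(phi, B)) * h2 +
      p$alpha * (volume(phi, g) - p$Vbar)^2
  }
  tot
}

#' Exclusion (overlap-penalty) energy
#'
#' `beta0 sum_m int h(phi0) h(phi_m) + sum_m sum_{n != m} beta(m,n)
#' int h(phi_n) h(phi_m)`; the double sum counts each unordered pair twice.
#'
#' @param state a [pf_state()].
#' @export
energy_E1 <- function(state) {
  h2 <- state$grid$h^2
  types <- vapply(state$params, `[[`, "", "type")
  hs <- lapply(seq_along(types), function(m) interp_h(state$phi[, , m]))
  h0 <- interp_h(state$phi0)
  tot <- state$tables$beta0 * sum(vapply(hs, function(hm) sum(h0 * hm), 0)) * h2
  N <- length(types)
  for (m in seq_len(N)) for (n in seq_len(N)) {
    if (n == m) next
    b <- state$tables$beta[types[m], types[n]]
    if (b != 0) tot <- tot + b * sum(hs[[m]] * hs[[n]]) * h2
  }
  tot
}

#' Global chamber-filling energy
#'
#' `alpha0 * (int (1 - h(phi0)) - sum_m V_m)^2`: the cells jointly fill the
#' interior of the chamber, the region not occupied by the epithelium.
#'
#' @param state a [pf_state()].
#' @export
energy_E2 <- function(state) {
  state$tables$alpha0 * (interior_area(state) - sum(cell_volumes(state)))^2
}

#' Adhesion (gradient-coupling) energy
#'
#' `gamma0 sum_m int grad h(phi0) . grad h(phi_m) + sum_m sum_{n != m}
#' gamma(m,n) int grad h(phi_m) . grad h(phi_n)`. Abutting interfaces have
#' opposing indicator gradients, so positive `gamma` rewards contact.
#'
#' @param state a [pf_state()].
#' @export
energy_E3 <- function(state) {
  g <- state$grid
  h2 <- g$h^2
  types <- vapply(state$params, `[[`, "", "type")
  hs <- lapply(seq_along(types), function(m) interp_h(state$phi[, , m]))
  h0 <- interp_h(state$phi0)
  tot <- state$tables$gamma0 *
    sum(vapply(hs, function(hm) face_dot_r(h0, hm, g$h), 0)) * h2
  N <- length(types)
  for (m in seq_len(N)) for (n in seq_len(N)) {
    if (n == m) next
    ga <- state$tables$gamma[types[m], types[n]]
    if (ga != 0) tot <- tot + ga * face_dot_r(hs[[m]], hs[[n]], g$h) * h2
  }
  tot
}

#' Energy breakdown of a state
#'
#' @param state a [pf_state()].
#' @return named numeric vector `E0`, `E1`, `E2`, `E3`, `total`.
#' @export
energy_breakdown <- function(state) {
  e <- c(E0 = energy_E0(state), E1 = energy_E1(state),
         E2 = energy_E2(state), E3 = energy_E3(state))
  c(e, total = sum(e))
}

#' Gradient-flow right-hand side for one cell
#'
#' Returns `dphi_m/dt = -mu * dE/dphi_m (+ external force)`, i.e.
#' `mu * (eps_m^2 lap(phi_m) + phi_m (1 - phi_m) (phi_m - 1/2 - 6 Fm))`
#' where `Fm` collects the volume penalty `2 alpha_m (V_m - Vbar_m)`,
#' epithelial exclusion `beta0 h(phi0)`, pairwise exclusion
#' `2 beta(m,n) h(phi_n)`, global filling `-2 alpha0 * deficit`, and adhesion
#' `-gamma0 lap h(phi0) - 2 gamma(m,n) lap h(phi_n)`. Every sign is derived
#' by descent from the energy terms, which the directional-derivative tests
#' verify term by term.
#'
#' @param state a [pf_state()].
#' @param m index of the dynamic cell.
#' @param external_force optional matrix added to the returned rate (guidance
#'   forces enter here and are not scaled by `mu`).
#' @param mu mobility of the phase field.
#' @return matrix of `dphi_m/dt`.
#' @export
variational_rhs <- function(state, m, external_force = NULL, mu = 1) {
  N <- dim(state$phi)[3]
  stopifnot(m >= 1, m <= N)
  r <- cpp_rhs_all(state$phi, state$phi0, pars_for_cpp(state, mu))[, , m]
  if (!is.null(external_force)) {
    check_field(external_force, state$grid)
    r <- r + external_force
  }
  r
}

# C++ energy (used for in-run trajectory logging); exposed for cross-checks
energy_breakdown_cpp <- function(state) {
  cpp_energy(state$phi, state$phi0, pars_for_cpp(state, 1))
}
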