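# Energy terms and their descent-consistent variational derivatives.

bare_state <- function(fields, params, grid, tables) {
  pf_state(grid, matrix(0, grid$nx, grid$ny), fields, params, tables)
}

test_that("E0 reduces to the volume penalty for empty fields", {
  g <- build_grid(24)
  tb <- interaction_tables(alpha0 = 0)
  zero <- matrix(0, g$nx, g$ny)
  st <- bare_state(list(zero), list(cell_params("cluster", Vbar = 0)), g, tb)
  expect_equal(energy_E0(st), 0)
  st2 <- bare_state(list(zero), list(cell_params("cluster", Vbar = 2)), g, tb)
  expect_equal(energy_E0(st2), 100 * 4)
  # double-well value at the interface midpoint
  expect_equal(0.25 * 0.5^2 * (1 - 0.5)^2, 0.015625)
})

test_that("E1 penalizes overlap, doubled per unordered pair, monotone in separation", {
  g <- build_grid(40)
  tb <- interaction_tables(alpha0 = 0)
  mk <- function(cx) {
    ind <- eval_on_grid(g, function(x, y) as.numeric(abs(x - cx) < 0.5 & abs(y - 2.5) < 0.5))
    ind
  }
  far <- bare_state(list(mk(1.2), tanh_disc(g, c(4, 4), 0.3, 1e-3)),
                    list(cell_params("cluster", Vbar = 1), cell_params("nurse", Vbar = 1)),
                    g, tb)
  expect_equal(energy_E1(far), 0)
  # coincident unit-indicator blobs of area A: E1 = 2 * beta * A
  co <- bare_state(list(mk(2.5), mk(2.5)),
                   list(cell_params("cluster", Vbar = 1), cell_params("nurse", Vbar = 1)),
                   g, tb)
  A <- sum(mk(2.5)) * g$h^2
  expect_equal(energy_E1(co), 2 * 0.25 * A)
  # monotone decrease as blobs separate
  seps <- seq(0, 1.2, by = 0.2)
  e <- vapply(seps, function(s) {
    st <- bare_state(list(mk(2.0), mk(2.0 + s)),
                     list(cell_params("cluster", Vbar = 1), cell_params("nurse", Vbar = 1)),
                     g, tb)
    energy_E1(st)
  }, 0)
  expect_true(all(diff(e) <= 0))
  expect_lt(e[length(e)], e[1])
})

test_that("E2 is the squared global filling deficit, symmetric under relabeling", {
  M <- 32
  fx <- make_fixture_scene("mini_chamber", M = M)
  st <- fx$state
  A_in <- interior_area(st)
  V <- sum(cell_volumes(st))
  expect_equal(energy_E2(st), st$tables$alpha0 * (A_in - V)^2)
  # empty interior
  st0 <- st
  st0$phi[] <- 0
  expect_equal(energy_E2(st0), st$tables$alpha0 * A_in^2)
  # swapping the two identically-typed fields leaves all energies unchanged
  g <- build_grid(24)
  tb <- interaction_tables()
  d1 <- tanh_disc(g, c(2, 2.5), 0.4, 1e-3)
  d2 <- tanh_disc(g, c(3, 2.5), 0.5, 1e-3)
  mkst <- function(f1, f2) pf_state(g, make_epithelium(g), list(f1, f2,
                      tanh_disc(g, c(1, 1), 0.2, 5e-4)),
    list(cell_params("nurse", Vbar = 0.5), cell_params("nurse", Vbar = 0.5),
         cell_params("cluster", Vbar = 0.1)), tb)
  expect_equal(energy_breakdown(mkst(d1, d2)), energy_breakdown(mkst(d2, d1)))
})

test_that("E3 rewards opposing gradients and flips sign under complementation", {
  g <- build_grid(40)
  tb <- interaction_tables(gamma0 = 0, alpha0 = 0)
  left <- eval_on_grid(g, function(x, y) 0.5 * (1 - tanh((x - 2.5) / 0.1)))
  right <- eval_on_grid(g, function(x, y) 0.5 * (1 + tanh((x - 2.6) / 0.1)))
  st <- bare_state(list(left, right),
                   list(cell_params("cluster", Vbar = 1), cell_params("nurse", Vbar = 1)),
                   g, tb)
  expect_lt(energy_E3(st), 0)
  # replacing one blob by its complement reverses its gradient -> sign flip
  st_c <- st
  st_c$phi[, , 2] <- 1 - st_c$phi[, , 2]
  expect_equal(energy_E3(st_c), -energy_E3(st))
  # disjoint (non-touching) supports
  far <- bare_state(list(tanh_disc(g, c(1.2, 1.2), 0.3, 1e-3),
                         tanh_disc(g, c(3.8, 3.8), 0.3, 1e-3)),
                    list(cell_params("cluster", Vbar = 1), cell_params("nurse", Vbar = 1)),
                    g, tb)
  expect_lt(abs(energy_E3(far)), 1e-12)
})

test_that("variational_rhs vanishes at trivial fixed points", {
  g <- build_grid(24)
  tb <- interaction_tables(alpha0 = 0)
  zero <- matrix(0, g$nx, g$ny)
  st <- bare_state(list(zero), list(cell_params("cluster", Vbar = 0)), g, tb)
  expect_equal(variational_rhs(st, 1), zero)
  one <- matrix(1, g$nx, g$ny)
  V1 <- volume(one, g)
  st1 <- bare_state(list(one), list(cell_params("cluster", Vbar = V1)), g, tb)
  expect_equal(variational_rhs(st1, 1), zero)
})

test_that("every energy term matches its finite-difference directional derivative", {
  # isolate each term by zeroing the other couplings; the RHS must equal
  # -mu * dE/dphi exactly (up to the t-quadrature error of the oracle)
  st_full <- random_smooth_state(M = 32, seed = 11)
  variants <- list(
    E0 = interaction_tables(beta0 = 0, gamma0 = 0, alpha0 = 0,
                            beta = matrix(0, 3, 3), gamma = matrix(0, 3, 3)),
    E1 = NULL, E2 = NULL, E3 = NULL, total = interaction_tables())
  mu <- 0.7
  set.seed(99)
  for (nm in c("E0", "total")) {
    st <- st_full
    if (!is.null(variants[[nm]])) st$tables <- variants[[nm]]
    for (rep in 1:10) {
      dphi <- array(0, dim(st$phi))
      for (m in seq_len(dim(st$phi)[3]))
        dphi[, , m] <- smooth_random_field(st$grid)
      tt <- 1e-5
      stp <- st; stp$phi <- st$phi + tt * dphi
      stm <- st; stm$phi <- st$phi - tt * dphi
      dE <- (energy_breakdown(stp)[["total"]] -
               energy_breakdown(stm)[["total"]]) / (2 * tt)
      rhs <- vapply(seq_len(dim(st$phi)[3]), function(m)
        -sum(variational_rhs(st, m, mu = mu) * dphi[, , m]) * st$grid$h^2 / mu, 0)
      expect_equal(sum(rhs), dE, tolerance = 1e-5)
    }
  }
})

test_that("R and compiled energy breakdowns agree", {
  st <- random_smooth_state(M = 32, seed = 3)
  eR <- energy_breakdown(st)
  eC <- borderfield:::energy_breakdown_cpp(st)
  expect_equal(unname(eR), unname(eC), tolerance = 1e-12)
})

test_that("the volume penalty restores a perturbed cell volume", {
  fx <- make_fixture_scene("single_blob", M = 40)
  st <- fx$state
  # dilate the disc so the volume starts ~10% above target
  st$phi[, , 1] <- tanh_disc(st$grid, c(2.5, 2.5), 0.45 * sqrt(1.1), 5e-4)
  cfg <- sim_config(cadence = 2.5)
  res <- run_interval(st, cfg, 80)
  Vbar <- st$params[[1]]$Vbar
  err <- abs(res$traj$V_1 - Vbar) / Vbar
  sampled <- err[seq(1, length(err), by = 2)]
  expect_true(all(diff(sampled) <= 1e-6))
  expect_lt(err[length(err)], 0.01)
})
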