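# Guidance forces: chemotaxis and tangential interface migration.

test_that("chemotaxis force vanishes without a gradient or a cluster", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  g <- st$grid
  zero <- matrix(0, g$nx, g$ny)
  expect_equal(f_chem(st$phi[, , st$cluster], uniform_field(g, 2)), zero)
  expect_equal(f_chem(zero, fx$chemo), zero)
})

test_that("chemotaxis force reduces to advection under a harmonic ramp", {
  # c = a x is harmonic, so -mu div(phi grad c) = -mu a dphi/dx
  fx <- make_fixture_scene("single_blob", M = 40)
  st <- fx$state
  g <- st$grid
  a <- 0.5
  ch <- borderfield:::new_chemo(eval_on_grid(g, function(x, y) 1 + a * x),
                                g, "analytic_linear")
  F <- f_chem(st$phi[, , 1], ch, mu_c = 0.045)
  expected <- -0.045 * a * gradient(st$phi[, , 1], g)$x
  expect_lt(max(abs(F - expected)), 1e-10)
})

test_that("TIM force is identically zero without substrate overlap or gradient", {
  fx <- make_fixture_scene("single_blob", M = 40)
  st <- fx$state
  g <- st$grid
  # add a far-away nurse cell: no overlap anywhere with the cluster
  far <- tanh_disc(g, c(4.3, 4.3), 0.25, 1e-3)
  st2 <- pf_state(g, st$phi0, list(st$phi[, , 1], far),
                  list(st$params[[1]], cell_params("nurse", Vbar = 0.2)),
                  st$tables)
  expect_equal(f_tim(st2, fx$chemo), matrix(0, g$nx, g$ny))
  # uniform field: sgn(0) = 0 gives an exactly zero force even with overlap
  fx2 <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  expect_equal(f_tim(fx2$state, uniform_field(g, 3)), matrix(0, g$nx, g$ny))
})

test_that("TIM force support is confined to the overlap region", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  fp <- force_params("tim")
  F <- f_tim(st, fx$chemo, fp = fp)
  ov <- st$phi[, , st$cluster] * borderfield:::substrate_sum(st, fp)
  # the divergence spreads the flux by one stencil cell beyond the overlap
  inside <- ov > fp$support_floor
  g <- st$grid
  dil <- inside
  for (dx in -1:1) for (dy in -1:1) {
    sh <- inside[pmin(pmax(seq_len(g$nx) + dx, 1), g$nx),
                 pmin(pmax(seq_len(g$ny) + dy, 1), g$ny)]
    dil <- dil | sh
  }
  expect_true(all(F[!dil] == 0))
  expect_gt(max(abs(F)), 0)
})

test_that("TIM force is invariant to the perp rotation convention", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  Fp <- f_tim(fx$state, fx$chemo, fp = force_params("tim", perp_sign = 1))
  Fm <- f_tim(fx$state, fx$chemo, fp = force_params("tim", perp_sign = -1))
  expect_equal(Fp, Fm, tolerance = 1e-14)
  # same for the inner-product formulation
  Ip <- f_tim_inner(fx$state, fx$chemo, fp = force_params("tim", perp_sign = 1))
  Im <- f_tim_inner(fx$state, fx$chemo, fp = force_params("tim", perp_sign = -1))
  expect_equal(Ip, Im, tolerance = 1e-14)
})

test_that("divergence of a rotated gradient vanishes; forms agree off the sign set", {
  # discrete identity: div(perp(grad f)) == 0 exactly for commuting stencils
  for (M in c(40, 80)) {
    g <- build_grid(M)
    f <- eval_on_grid(g, function(x, y) exp(-((x - 2.4)^2 + (y - 2.7)^2) / 0.4))
    pg <- perp(gradient(f, g))
    div <- gradient(pg$x, g)$x + gradient(pg$y, g)$y
    expect_lt(max(abs(div)), 1e-11)
  }
  # f_tim (divergence form) vs f_tim_inner: agreement to stencil accuracy
  # away from sign discontinuities, converging at second order; interfaces
  # widened so both resolutions sit in the asymptotic regime
  err <- vapply(c(80, 160), function(M) {
    g <- build_grid(M)
    st <- pf_state(g, matrix(0, g$nx, g$ny),
                   list(tanh_disc(g, c(2.2, 2.9), 0.6, 0.01),
                        tanh_disc(g, c(2.6, 1.9), 0.9, 0.01)),
                   list(cell_params("cluster", Vbar = 1, eps2 = 0.01),
                        cell_params("nurse", Vbar = 2, eps2 = 0.01)),
                   interaction_tables(alpha0 = 0))
    chemo <- borderfield:::new_chemo(
      eval_on_grid(g, function(x, y) 1 + 0.5 * x), g, "analytic_linear")
    fp <- force_params("tim", support_floor = 0)
    Fd <- f_tim(st, chemo, fp = fp)
    Fi <- f_tim_inner(st, chemo, fp = fp)
    # mask nodes adjacent to a sign change of grad c . perp(grad phic)
    gc <- gradient(chemo$c, g)
    tv <- perp(gradient(st$phi[, , st$cluster], g))
    s <- sign(gc$x * tv$x + gc$y * tv$y)
    away <- matrix(TRUE, g$nx, g$ny)
    w <- max(1L, round(0.3 / g$h))
    for (dx in -w:w) for (dy in -w:w) {
      sh <- s[pmin(pmax(seq_len(g$nx) + dx, 1), g$nx),
              pmin(pmax(seq_len(g$ny) + dy, 1), g$ny)]
      away <- away & (sh == s)
    }
    max(abs((Fd - Fi)[away]))
  }, 0)
  expect_gt(err[1] / err[2], 3.5)
})

test_that("saturation makes TIM insensitive to concentration rescaling", {
  # in the saturated regime, c -> 10 c barely changes rho (hence f_tim),
  # while f_chem scales by 10
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  g <- st$grid
  base <- borderfield:::new_chemo(eval_on_grid(g, function(x, y) 4 + 0.5 * x),
                                  g, "analytic_linear")
  scaled <- borderfield:::new_chemo(10 * base$c, g, "analytic_linear")
  Ft1 <- f_tim(st, base)
  Ft10 <- f_tim(st, scaled)
  expect_lt(abs(max(abs(Ft10)) - max(abs(Ft1))) / max(abs(Ft1)), 0.05)
  Fc1 <- f_chem(st$phi[, , st$cluster], base)
  Fc10 <- f_chem(st$phi[, , st$cluster], scaled)
  expect_equal(max(abs(Fc10)) / max(abs(Fc1)), 10, tolerance = 1e-6)
})

test_that("mirror symmetry: reflected scenes give reflected forces", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  g <- st$grid
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  st_f <- st
  st_f$phi0 <- flip(st$phi0)
  for (m in seq_len(dim(st$phi)[3])) st_f$phi[, , m] <- flip(st$phi[, , m])
  ch_f <- fx$chemo
  ch_f$c <- flip(fx$chemo$c)
  expect_equal(f_chem(st_f$phi[, , st$cluster], ch_f),
               flip(f_chem(st$phi[, , st$cluster], fx$chemo)), tolerance = 1e-12)
  expect_equal(f_tim(st_f, ch_f), flip(f_tim(st, fx$chemo)), tolerance = 1e-12)
})

test_that("external_force dispatches only to the cluster", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  none <- external_force(st, fx$chemo, fp = force_params("none"))
  expect_true(all(vapply(none, is.null, TRUE)))
  chem <- external_force(st, fx$chemo, fp = force_params("chem"))
  expect_false(is.null(chem[[st$cluster]]))
  expect_true(all(vapply(seq_along(chem)[-st$cluster],
                         function(i) is.null(chem[[i]]), TRUE)))
  tim_u <- external_force(st, uniform_field(st$grid, 1),
                          fp = force_params("tim"))
  expect_equal(tim_u[[st$cluster]], matrix(0, st$grid$nx, st$grid$ny))
})
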