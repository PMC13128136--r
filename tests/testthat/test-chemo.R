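# Steady chemoattractant profiles and receptor activation.

const_geom <- function(k = 1, cL = 5, L = 5)
  channel_geometry(r = function(x) rep(0.5, length(x)), D = 1, k = k,
                   c_posterior = cL, x_range = c(0, L))

cosh_exact <- function(x, k, D, cL, L) cL * cosh(sqrt(k / D) * x) / cosh(sqrt(k / D) * L)

test_that("zero degradation with constant cross-section gives a flat profile", {
  pr <- solve_steady_1d(const_geom(k = 0), 128)
  expect_equal(pr$c, rep(5, 128), tolerance = 1e-12)
})

test_that("constant-A profile matches the cosh closed form at second order", {
  pr <- solve_steady_1d(const_geom(), 512)
  exact <- cosh_exact(pr$x, 1, 1, 5, 5)
  expect_lt(max(abs(pr$c - exact) / exact), 1e-3)
  # observed convergence order >= 1.9
  errs <- vapply(c(64, 128, 256), function(n) {
    p <- solve_steady_1d(const_geom(), n)
    max(abs(p$c - cosh_exact(p$x, 1, 1, 5, 5)))
  }, 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 1.9))
})

test_that("a widened junction lowers concentration and flattens the gradient", {
  base <- solve_steady_1d(const_geom(), 512)
  widened <- channel_geometry(
    r = function(x) 0.5 + 1.5 * (abs(x - 2.5) < 0.4), D = 1, k = 1,
    c_posterior = 5, x_range = c(0, 5))
  wd <- solve_steady_1d(widened, 512)
  mid <- wd$x > 2.1 & wd$x < 2.9
  expect_true(all(wd$c[mid] < base$c[mid]))
  slope <- function(p) diff(p$c) / diff(p$x)
  expect_lt(max(abs(slope(wd)[mid[-1]])), max(abs(slope(base)[mid[-1]])))
})

test_that("solver rejects a collapsed channel", {
  bad <- channel_geometry(r = function(x) 0.5 - 0.6 * (x > 2), k = 1)
  expect_error(solve_steady_1d(bad), "positive")
})

test_that("extend_to_2d copies the profile across y", {
  g <- build_grid(32)
  pr <- data.frame(x = seq(0, 5, length.out = 64), c = 2)
  ch <- extend_to_2d(pr, g)
  expect_equal(ch$c, matrix(2, g$nx, g$ny))
  pr2 <- solve_steady_1d(const_geom(), 256)
  ch2 <- extend_to_2d(pr2, g)
  expect_equal(max(abs(ch2$c[, 1] - ch2$c[, g$ny])), 0)       # no y-dependence
  expect_equal(ch2$c[, 3],
               stats::approx(pr2$x, pr2$c, xout = g$x)$y)
  short <- data.frame(x = seq(1, 4, length.out = 16), c = 1)
  expect_error(extend_to_2d(short, g), "cover")
  expect_silent(extend_to_2d(short, g, extrapolate = "clamp"))
})

test_that("analytic dorsal field has the prescribed structure", {
  g <- build_grid(48)
  ch <- analytic_dorsal_field(g)
  ix <- which.min(abs(g$x - 1))
  # evaluate formula independently at a node
  expect_equal(ch$c[ix, 5], cosh(1.5 * g$x[ix]) + 1e-4 * cosh(g$y[5]))
  # strictly increasing in x at fixed y, dorsal bias in y
  expect_true(all(diff(ch$c[, 10]) > 0))
  expect_true(all(diff(ch$c[10, ]) > 0))
  # at the origin corner the value approaches 1 + 1e-4
  g2 <- build_grid(199)
  ch2 <- analytic_dorsal_field(g2)
  expect_equal(ch2$c[1, 1], cosh(1.5 * g2$h) + 1e-4 * cosh(g2$h), tolerance = 1e-12)
})

test_that("scale_profile scales the linear problem pointwise", {
  g <- build_grid(32)
  geom <- const_geom()
  ch <- extend_to_2d(solve_steady_1d(geom), g)
  expect_equal(scale_profile(ch, 1, geom)$c, ch$c)
  sc <- scale_profile(ch, 0.2, geom)
  expect_equal(sc$c, 0.2 * ch$c, tolerance = 1e-10)
  # gradient magnitude strictly decreases with the factor
  gmax <- vapply(c(1, 0.6, 0.2), function(f)
    max(abs(gradient(scale_profile(ch, f, geom)$c, g)$x)), 0)
  expect_true(all(diff(gmax) < 0))
  # commutes with extend_to_2d
  pr <- solve_steady_1d(geom)
  geom2 <- geom; geom2$c_posterior <- geom$c_posterior * 0.3
  pr2 <- solve_steady_1d(geom2)
  expect_equal(scale_profile(ch, 0.3, geom)$c, extend_to_2d(pr2, g)$c,
               tolerance = 1e-12)
})

test_that("receptor activation is a saturating Hill-like response", {
  p <- receptor_params()
  expect_equal(receptor_activation(0, p), 0)
  expect_equal(receptor_activation(1, p), 1 / (1.01 * 1.05))
  cs <- seq(0, 50, by = 0.01)
  rho <- receptor_activation(cs, p)
  expect_true(all(diff(rho) > 0))                 # monotone for the defaults
  expect_true(all(rho < p$s))                     # bounded below s
  expect_equal(receptor_activation(1e6, p), p$s, tolerance = 1e-5)
  expect_error(receptor_activation(-0.1, p), "negative")
})

test_that("receptor regime check flags degenerate landscapes", {
  g <- build_grid(32)
  expect_false(check_receptor_regime(uniform_field(g, 1))$ok)
  # saturated everywhere
  expect_false(check_receptor_regime(uniform_field(g, 50))$anterior_ok)
  # the default baseline landscape satisfies the regime
  ch <- extend_to_2d(solve_steady_1d(channel_geometry(), 4096), g, "clamp")
  reg <- check_receptor_regime(ch)
  expect_true(reg$ok)
  expect_lt(reg$rho_anterior, 0.1)
  expect_gt(reg$rho_posterior, 0.8)
})
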