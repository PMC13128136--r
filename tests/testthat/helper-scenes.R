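# Shared small scenes and memoized expensive runs (computed once per session).

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# a smooth random field on a grid (random Fourier-free bump mixture)
smooth_random_field <- function(grid, n_bumps = 6, amp = 0.3) {
  f <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(n_bumps)) {
    cx <- stats::runif(1, grid$extent[1], grid$extent[2])
    cy <- stats::runif(1, grid$extent[3], grid$extent[4])
    s <- stats::runif(1, 0.3, 0.9)
    a <- stats::runif(1, -amp, amp)
    f <- f + a * eval_on_grid(grid, function(x, y)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
  }
  f
}

# random smooth state for functional-derivative oracles: fixture scene with
# perturbed fields so nothing sits exactly at a critical point
random_smooth_state <- function(M = 32, seed = 7) {
  withr::with_seed(seed, {
    fx <- make_fixture_scene("mini_chamber", M = M)
    st <- fx$state
    for (m in seq_len(dim(st$phi)[3])) {
      st$phi[, , m] <- pmin(pmax(
        st$phi[, , m] + 0.15 * smooth_random_field(st$grid), -0.05), 1.05)
    }
    st
  })
}
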