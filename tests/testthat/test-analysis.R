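# Trajectory metrics.

test_that("centroid locates symmetric discs and translates with them", {
  g <- build_grid(63)
  d <- tanh_disc(g, c(1.0, 2.5), 0.4, 1e-3)
  expect_equal(unname(centroid(d, g)), c(1.0, 2.5), tolerance = g$h / 10)
  d2 <- tanh_disc(g, c(1.8, 3.1), 0.4, 1e-3)
  expect_equal(unname(centroid(d2, g) - centroid(d, g)), c(0.8, 0.6),
               tolerance = g$h / 5)
  # close to the 0.5-threshold binary centroid for a sharp disc
  bin <- (d > 0.5) * 1
  cb <- c(sum(bin * g$x) / sum(bin), sum(sweep(bin, 2, g$y, `*`)) / sum(bin))
  expect_lt(max(abs(centroid(d, g) - cb)), g$h)
  expect_error(centroid(matrix(0, g$nx, g$ny), g), "vanished")
})

test_that("speed series recovers constant and zero speeds", {
  tr <- data.frame(t = seq(0, 100, by = 5),
                   x_c = seq(0, 2, length.out = 21),
                   y_c = rep(1, 21))
  sp <- speed_series(tr, window = 1)
  expect_equal(sp$speed, rep(0.02, 21), tolerance = 1e-12)
  expect_equal(sp$speed_ap, rep(0.02, 21), tolerance = 1e-12)
  tr0 <- data.frame(t = 0:10, x_c = rep(2, 11), y_c = rep(3, 11))
  expect_equal(speed_series(tr0)$speed, rep(0, 11))
  # arc speed includes the y-component; A-P component is signed
  tr2 <- data.frame(t = 0:10, x_c = seq(0, -1, length.out = 11),
                    y_c = seq(0, 1, length.out = 11))
  sp2 <- speed_series(tr2, window = 1)
  expect_equal(sp2$speed, rep(sqrt(2) * 0.1, 11), tolerance = 1e-12)
  expect_equal(sp2$speed_ap, rep(-0.1, 11), tolerance = 1e-12)
})

test_that("overlap field sums unordered pairs once", {
  fx <- make_fixture_scene("two_blob_overlap", M = 40)
  ov <- overlap_field(fx$state)
  expect_gt(sum(ov) * fx$state$grid$h^2, 0)
  expect_equal(ov, fx$state$phi[, , 1] * fx$state$phi[, , 2])
  # disjoint scene
  g <- build_grid(32)
  st <- pf_state(g, matrix(0, g$nx, g$ny),
                 list(tanh_disc(g, c(1, 1), 0.3, 1e-3),
                      tanh_disc(g, c(4, 4), 0.3, 1e-3)),
                 list(cell_params("cluster", Vbar = 0.3),
                      cell_params("nurse", Vbar = 0.3)),
                 interaction_tables(alpha0 = 0))
  expect_lt(max(overlap_field(st)), 1e-12)
  # coincident identical discs give the squared field
  st$phi[, , 2] <- st$phi[, , 1]
  expect_equal(overlap_field(st), st$phi[, , 1]^2)
})

test_that("arrival detection thresholds the oocyte overlap", {
  tr <- data.frame(t = seq(0, 90, by = 10),
                   ov_oocyte = c(0, 0, 0.001, 0.004, 0.01, 0.02, 0.05,
                                 0.08, 0.1, 0.12))
  expect_equal(arrival_time(tr, threshold = 0.015), 50)
  expect_true(is.na(arrival_time(tr, threshold = Inf)))
  expect_true(is.na(arrival_time(tr, threshold = 0.5)))
})

test_that("net displacement is the first-to-last centroid distance", {
  tr <- data.frame(t = 0:2, x_c = c(0, 5, 3), y_c = c(0, 5, 4))
  expect_equal(net_displacement(tr), 5)
  tr0 <- data.frame(t = 0:2, x_c = rep(1, 3), y_c = rep(1, 3))
  expect_equal(net_displacement(tr0), 0)
})

test_that("speed peak counting respects prominence", {
  s <- c(0, 1, 0, 1, 0)                       # two prominent peaks
  expect_equal(count_speed_peaks(s), 2L)
  s2 <- c(0, 1, 0.99, 1.001, 0)               # middle dip is not prominent
  expect_equal(count_speed_peaks(s2, min_prominence = 0.05), 1L)
  expect_equal(count_speed_peaks(rep(1, 10)), 0L)
  expect_equal(count_speed_peaks(seq(0, 1, 0.1)), 0L)  # monotone: no interior max
})

test_that("mirror reflection maps the trajectory metrics consistently", {
  fx <- make_fixture_scene("blob_on_substrate_linear_c", M = 40)
  st <- fx$state
  g <- st$grid
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  cfg <- sim_config(cadence = 5)
  fp <- force_params("tim")
  r <- run_interval(st, cfg, 60, chemo = fx$chemo, fp = fp)
  st_f <- st
  st_f$phi0 <- flip(st$phi0)
  for (m in seq_len(dim(st$phi)[3])) st_f$phi[, , m] <- flip(st$phi[, , m])
  ch_f <- fx$chemo
  ch_f$c <- flip(fx$chemo$c)
  r_f <- run_interval(st_f, cfg, 60, chemo = ch_f, fp = fp)
  Ly <- g$extent[3] + g$extent[4]
  expect_equal(r_f$traj$y_c, Ly - r$traj$y_c, tolerance = 1e-9)
  expect_equal(r_f$traj$x_c, r$traj$x_c, tolerance = 1e-9)
  expect_equal(speed_series(r_f$traj)$speed, speed_series(r$traj)$speed,
               tolerance = 1e-9)
})
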