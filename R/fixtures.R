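# Small scenes for fast tests and examples.

#' Build a small fixture scene
#'
#' Tiny scenes on grids of at most 48 x 48 nodes, each completing a 500-step
#' run in seconds:
#'
#' * `single_blob` - one cluster cell alone in the chamber (global filling
#'   off), for fixed-point and drift checks.
#' * `two_blob_overlap` - a cluster and a nurse cell with overlapping
#'   initial discs.
#' * `blob_on_substrate_linear_c` - a cluster resting on a large nurse
#'   substrate under a linear-in-x concentration ramp; the standard scene
#'   for TIM direction and convention tests.
#' * `mini_chamber` - one nurse cell, the cluster and an oocyte filling a
#'   reduced chamber; the smallest scene with all energy terms active.
#'
#' @param kind fixture name.
#' @param M grid resolution (<= 48).
#' @return list with `state` (a [pf_state()]) and `chemo` (`pf_chemo` or
#'   `NULL`).
#' @export
make_fixture_scene <- function(kind = c("single_blob", "two_blob_overlap",
                                        "blob_on_substrate_linear_c",
                                        "mini_chamber"),
                               M = 48) {
  kind <- match.arg(kind)
  stopifnot(M <= 48, M >= 24)
  grid <- build_grid(M)
  no_fill <- interaction_tables(alpha0 = 0)
  linear_c <- function() new_chemo(eval_on_grid(grid, function(x, y) 1 + 0.5 * x),
                                   grid, "analytic_linear")
  shape <- chamber_shape()
  switch(kind,
    single_blob = {
      r <- 0.45
      roster <- data.frame(name = "cluster", type = "cluster",
                           x = 2.5, y = 2.5, r = r)
      st <- init_with_targets(grid, roster, no_fill, shape)
      list(state = st, chemo = linear_c())
    },
    two_blob_overlap = {
      roster <- data.frame(name = c("cluster", "nurse1"),
                           type = c("cluster", "nurse"),
                           x = c(2.2, 2.9), y = c(2.5, 2.5),
                           r = c(0.4, 0.5))
      st <- suppressWarnings(init_with_targets(grid, roster, no_fill, shape))
      list(state = st, chemo = linear_c())
    },
    blob_on_substrate_linear_c = {
      roster <- data.frame(name = c("cluster", "nurse1"),
                           type = c("cluster", "nurse"),
                           x = c(2.2, 2.6), y = c(2.9, 2.0),
                           r = c(0.35, 0.85))
      st <- init_with_targets(grid, roster, no_fill, shape)
      list(state = st, chemo = linear_c())
    },
    mini_chamber = {
      mshape <- chamber_shape(x1 = 2.2, x2 = 2.8, R = 1.35)
      roster <- data.frame(name = c("cluster", "nurse1", "oocyte"),
                           type = c("cluster", "nurse", "oocyte"),
                           x = c(1.35, 2.3, 3.5), y = c(2.5, 2.5, 2.5),
                           r = c(0.33, 0.85, 0.95))
      # volume-matched packing necessarily overlaps before relaxation
      st <- suppressWarnings(init_state(grid, roster, interaction_tables(),
                                        mshape))
      list(state = st, chemo = linear_c())
    })
}

# like init_state but with target volumes equal to the initial disc areas
# (scenes that do not fill the chamber would otherwise be forced to grow)
init_with_targets <- function(grid, roster, tables, shape) {
  phi0 <- make_epithelium(grid, shape)
  fields <- lapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    tanh_disc(grid, c(p$x, p$y), p$r,
              if (p$type == "cluster") 5e-4 else 1e-3)
  })
  params <- lapply(seq_len(nrow(roster)), function(i)
    cell_params(roster$type[i], Vbar = pi * roster$r[i]^2))
  pf_state(grid, phi0, fields, params, tables)
}
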