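# Scene construction, explicit time stepping, equilibration, scenarios.

#' Chamber shape (stadium) for the static epithelium
#'
#' A stadium (segment of half-length along the A-P axis, capped by
#' semicircles) has an exact signed distance, which keeps the epithelial
#' interface profile clean. The default spans x from 0.1 to 4.9 and
#' y from 0.75 to 4.25 inside the square domain.
#'
#' @param x1,x2 segment endpoints on the midline.
#' @param R cap/half-width radius.
#' @param y_mid midline height.
#' @export
chamber_shape <- function(x1 = 1.85, x2 = 3.15, R = 1.75, y_mid = 2.5) {
  stopifnot(x2 >= x1, R > 0)
  structure(list(x1 = x1, x2 = x2, R = R, y_mid = y_mid),
            class = "pf_shape")
}

#' Analytic area of a chamber shape
#' @param shape a [chamber_shape()].
#' @export
chamber_area <- function(shape) {
  pi * shape$R^2 + 2 * shape$R * (shape$x2 - shape$x1)
}

#' Static epithelium field
#'
#' Smoothed indicator of the chamber exterior: `phi0 ~ 0` inside, `~ 1`
#' outside, with an equilibrium tanh transition of width set by `eps2`
#' (default: the nurse-cell interface scale).
#'
#' @param grid grid.
#' @param shape a [chamber_shape()].
#' @param eps2 interface-width parameter of the transition.
#' @export
make_epithelium <- function(grid, shape = chamber_shape(), eps2 = 1e-3) {
  eps <- sqrt(eps2)
  eval_on_grid(grid, function(x, y) {
    px <- pmin(pmax(x, shape$x1), shape$x2)   # closest point on the segment
    d <- sqrt((x - px)^2 + (y - shape$y_mid)^2) - shape$R
    0.5 * (1 + tanh(d / (2 * sqrt(2) * eps)))
  })
}

#' Default cell roster
#'
#' Six nurse cells of heterogeneous size in two rows flanking a midline
#' channel, the border cell cluster at the anterior end of the channel, and
#' a larger oocyte at the posterior. Positions and radii are presentation
#' defaults for the qualitative layout; target volumes are assigned at
#' initialization in proportion to disc area, rescaled so the roster fills
#' the chamber interior.
#'
#' @return data.frame with columns `name`, `type`, `x`, `y`, `r`.
#' @export
default_roster <- function() {
  data.frame(
    name = c("cluster", "nurse1", "nurse2", "nurse3",
             "nurse4", "nurse5", "nurse6", "oocyte"),
    type = c("cluster", rep("nurse", 6), "oocyte"),
    x = c(0.75, 1.30, 2.30, 3.15, 1.30, 2.30, 3.15, 3.95),
    y = c(2.50, 3.30, 3.35, 3.25, 1.70, 1.65, 1.75, 2.50),
    r = c(0.28, 0.68, 0.72, 0.62, 0.64, 0.70, 0.63, 1.05),
    stringsAsFactors = FALSE)
}

#' Initialize the multicellular state
#'
#' Target volumes are the roster disc areas rescaled to sum to the chamber
#' interior area, so the global filling constraint and the per-cell volume
#' targets are mutually consistent. Each cell starts as a circular tanh disc
#' at the volume-matched radius `sqrt(Vbar/pi)` (times `init_scale`):
#' starting at target volume keeps the stiff volume penalty acting only on
#' fluctuations, which the explicit scheme requires; equilibration then
#' relaxes the circular shapes into the packed configuration.
#'
#' @param grid grid.
#' @param roster data.frame as [default_roster()]; radii set the relative
#'   size weights and the layout.
#' @param tables [interaction_tables()].
#' @param shape [chamber_shape()].
#' @param init_scale initial radius as a fraction of the volume-matched
#'   radius.
#' @param overlap_warn warn if any initial pair overlap integral exceeds
#'   this fraction of the smaller cell's initial volume.
#' @export
init_state <- function(grid, roster = default_roster(),
                       tables = interaction_tables(),
                       shape = chamber_shape(),
                       init_scale = 1, overlap_warn = 0.3) {
  stopifnot(all(roster$type %in% PF_TYPES))
  phi0 <- make_epithelium(grid, shape)
  A_in <- sum(1 - interp_h(phi0)) * grid$h^2
  w <- pi * roster$r^2
  Vbar <- A_in * w / sum(w)
  oc <- roster$type == "oocyte"
  if (any(oc) && any(roster$type == "nurse") &&
      min(Vbar[oc]) <= max(Vbar[roster$type == "nurse"]))
    warning("oocyte target volume does not exceed every nurse cell target")
  fields <- lapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    tanh_disc(grid, c(p$x, p$y), sqrt(Vbar[i] / pi) * init_scale,
              if (p$type == "cluster") 5e-4 else 1e-3)
  })
  params <- lapply(seq_len(nrow(roster)), function(i)
    cell_params(roster$type[i], Vbar = Vbar[i]))
  # initial collision check
  h2 <- grid$h^2
  for (i in seq_along(fields)) for (j in seq_along(fields)) {
    if (j <= i) next
    ov <- sum(fields[[i]] * fields[[j]]) * h2
    vmin <- min(sum(fields[[i]]), sum(fields[[j]])) * h2
    if (ov > overlap_warn * vmin)
      warning(sprintf("initial overlap between %s and %s (%.2f of smaller volume)",
                      roster$name[i], roster$name[j], ov / vmin))
  }
  pf_state(grid, phi0, fields, params, tables)
}

#' Explicit-scheme stability limit
#'
#' `dt_max = h^2 / (2 mu eps2)` for the diffusive part of one cell's
#' evolution; the engine refuses configurations whose `dt` exceeds the
#' minimum over cells.
#'
#' @param h mesh size.
#' @param mu mobility.
#' @param eps2 interface-width parameter.
#' @export
stability_limit <- function(h, mu, eps2) {
  stopifnot(h > 0, mu > 0, eps2 > 0)
  h^2 / (2 * mu * eps2)
}

#' Simulation configuration
#'
#' @param dt time step (default 0.05, the reference value for `h = 0.05`).
#' @param mu phase-field mobility. The default 0.05 keeps the explicit
#'   scheme stable against the stiff volume-penalty mode introduced by
#'   `alpha_m = 100` (see the methods vignette); timescales below are
#'   quoted at this mobility.
#' @param t_equilibrate force-free relaxation end time.
#' @param t_migrate migration phase duration (`NA` lets [run_scenario()]
#'   pick the preset's window).
#' @param cadence model-time interval between trajectory records.
#' @param seed integer seed for optional stochastic perturbations.
#' @export
sim_config <- function(dt = 0.05, mu = 0.05, t_equilibrate = 2000,
                       t_migrate = 4000, cadence = 10, seed = 1L) {
  stopifnot(dt > 0, mu > 0, t_equilibrate >= 0,
            is.na(t_migrate) || t_migrate >= 0, cadence > 0)
  structure(list(dt = dt, mu = mu, t_equilibrate = t_equilibrate,
                 t_migrate = t_migrate, cadence = cadence,
                 seed = as.integer(seed)),
            class = "pf_config")
}

check_stability <- function(state, config) {
  lim <- min(vapply(state$params, function(p)
    stability_limit(state$grid$h, config$mu, p$eps2), 0))
  if (config$dt > lim)
    stop(sprintf("dt = %g exceeds the stability limit %g", config$dt, lim))
  invisible(lim)
}

traj_names <- function(N) {
  c("t", "x_c", "y_c", paste0("V_", seq_len(N)),
    "E0", "E1", "E2", "E3", "E_total", "ov_substrate", "ov_oocyte")
}

run_ctrl <- function(state, config, nsteps, record_every, chemo, rp, fp) {
  mode <- if (is.null(fp)) 0L else switch(fp$mode, none = 0L, chem = 1L, tim = 2L)
  sub_idx <- integer(0)
  rho <- gcx <- gcy <- matrix(0, 1, 1)
  if (mode > 0L) {
    gc <- gradient(chemo$c, state$grid)
    gcx <- gc$x; gcy <- gc$y
    rho <- receptor_activation(chemo$c, rp)
    if (mode == 2L) {
      sub_idx <- which(vapply(state$params, `[[`, "", "type") %in% fp$substrate)
      sub_idx <- setdiff(sub_idx, state$cluster)
      if (length(sub_idx) == 0) stop("empty substrate set")
    }
  }
  list(dt = config$dt, nsteps = as.integer(nsteps),
       record_every = as.integer(record_every), t0 = state$time,
       force_mode = mode, force_cell = state$cluster - 1L,
       mu_c = if (is.null(fp)) 0 else fp$mu_c,
       mubar_c = if (is.null(fp)) 0 else fp$mubar_c,
       rho = rho, gcx = gcx, gcy = gcy,
       substrate = as.integer(sub_idx - 1L),
       perp_sign = if (is.null(fp)) 1 else fp$perp_sign,
       sgn_width = if (is.null(fp)) 0 else fp$sgn_width,
       support_floor = if (is.null(fp)) 0 else fp$support_floor,
       cluster = state$cluster - 1L,
       oocyte = if (is.na(state$oocyte)) -1L else state$oocyte - 1L,
       nurse = as.integer(state$nurse - 1L),
       x = state$grid$x, y = state$grid$y)
}

#' Advance the system over a time interval
#'
#' Forward-Euler integration of all dynamic cells under the energy gradient
#' flow plus the configured guidance force, with trajectory records every
#' `cadence` time units. Aborts (with the last recorded state retained) if
#' non-finite values appear.
#'
#' @param state a [pf_state()].
#' @param config a [sim_config()].
#' @param t_end absolute end time.
#' @param chemo `pf_chemo` or `NULL`.
#' @param rp [receptor_params()].
#' @param fp [force_params()] or `NULL` for force-free relaxation.
#' @return list with updated `state`, trajectory data.frame `traj`, and
#'   `overshoot` (max excursion of any field beyond the unit interval).
#' @export
run_interval <- function(state, config, t_end, chemo = NULL,
                         rp = receptor_params(), fp = NULL) {
  check_stability(state, config)
  nsteps <- max(0L, as.integer(round((t_end - state$time) / config$dt)))
  record_every <- max(1L, as.integer(round(config$cadence / config$dt)))
  if (nsteps == 0L)
    return(list(state = state,
                traj = as.data.frame(stats::setNames(
                  as.list(rep(NA_real_, length(traj_names(dim(state$phi)[3])))),
                  traj_names(dim(state$phi)[3])))[0, ],
                overshoot = c(below = 0, above = 0)))
  nsteps <- as.integer(ceiling(nsteps / record_every) * record_every)
  res <- cpp_run(state$phi, state$phi0, pars_for_cpp(state, config$mu),
                 run_ctrl(state, config, nsteps, record_every, chemo, rp, fp))
  if (!res$ok)
    warning("integration aborted at t = ", res$time, ": ", res$message)
  state$phi <- res$phi
  state$time <- res$time
  traj <- as.data.frame(res$traj)
  names(traj) <- traj_names(dim(state$phi)[3])
  list(state = state, traj = traj, overshoot = res$overshoot, ok = res$ok)
}

#' Advance a single time step
#'
#' @inheritParams run_interval
#' @export
pf_step <- function(state, config, chemo = NULL, rp = receptor_params(),
                    fp = NULL) {
  check_stability(state, config)
  res <- cpp_run(state$phi, state$phi0, pars_for_cpp(state, config$mu),
                 run_ctrl(state, config, 1L, 1L, chemo, rp, fp))
  state$phi <- res$phi
  state$time <- res$time
  state
}

#' Force-free equilibration
#'
#' Relaxes the scene without guidance forces until `t_end` (default: the
#' config's equilibration time), optionally stopping early once the total
#' energy plateaus. Reports per-cell relative volume errors and the energy
#' plateau metric.
#'
#' With `grow_time > 0` the per-cell volume targets are ramped linearly
#' from the initial disc volumes to their final values over that interval
#' (quasi-static growth), then held fixed. Growing the cells into contact
#' avoids two failure modes of starting at full volume: the stiff volume
#' penalty reacting to a large initial deficit, and deep field overlap,
#' where the exclusion force (proportional to `h'(phi)`) vanishes in the
#' bulk and merged cells cannot separate.
#'
#' @param state a [pf_state()].
#' @param config a [sim_config()].
#' @param t_end override of the equilibration end time.
#' @param plateau_tol if not `NULL`, stop once the relative energy change
#'   over a cadence window drops below this value (checked after growth).
#' @param grow_time duration of the quasi-static growth ramp (0 = targets
#'   fixed throughout, for scenes initialized at target volume).
#' @return list of class `pf_equilibration`: `state`, `traj`, `vol_error`
#'   (per-cell `|V - Vbar|/Vbar`), `plateau` (last relative energy change).
#' @export
equilibrate <- function(state, config = sim_config(), t_end = NULL,
                        plateau_tol = NULL, grow_time = 0) {
  t_end <- if (is.null(t_end)) config$t_equilibrate else t_end
  traj0 <- NULL
  if (grow_time > 0) {
    t_grow_end <- min(state$time + grow_time, t_end)
    Vbar_final <- vapply(state$params, `[[`, 0, "Vbar")
    V0 <- cell_volumes(state)
    chunk <- config$cadence
    t_start <- state$time
    while (state$time < t_grow_end - 1e-9) {
      tnext <- min(state$time + chunk, t_grow_end)
      frac <- (tnext - t_start) / grow_time
      for (m in seq_along(state$params))
        state$params[[m]]$Vbar <- V0[m] + frac * (Vbar_final[m] - V0[m])
      res <- run_interval(state, config, tnext)
      state <- res$state
      traj0 <- if (is.null(traj0)) res$traj else rbind(traj0, res$traj[-1, ])
    }
    for (m in seq_along(state$params)) state$params[[m]]$Vbar <- Vbar_final[m]
  }
  if (is.null(plateau_tol)) {
    res <- run_interval(state, config, t_end)
    traj <- res$traj
    state <- res$state
  } else {
    chunk <- max(config$cadence * 10, 20 * config$dt)
    traj <- NULL
    repeat {
      tnext <- min(state$time + chunk, t_end)
      res <- run_interval(state, config, tnext)
      state <- res$state
      traj <- if (is.null(traj)) res$traj else rbind(traj, res$traj[-1, ])
      ne <- nrow(traj)
      rel <- abs(traj$E_total[ne] - traj$E_total[ne - 1]) /
        max(abs(traj$E_total[ne]), .Machine$double.eps)
      if (state$time >= t_end || rel < plateau_tol) break
    }
  }
  if (!is.null(traj0)) traj <- rbind(traj0, traj[-1, ])
  Vbar <- vapply(state$params, `[[`, 0, "Vbar")
  V <- cell_volumes(state)
  ne <- nrow(traj)
  plateau <- abs(traj$E_total[ne] - traj$E_total[ne - 1]) /
    max(abs(traj$E_total[ne]), .Machine$double.eps)
  structure(list(state = state, traj = traj,
                 vol_error = abs(V - Vbar) / Vbar, plateau = plateau),
            class = "pf_equilibration")
}

#' @export
print.pf_equilibration <- function(x, ...) {
  cat(sprintf("<pf_equilibration> t = %g, max |V-Vbar|/Vbar = %.3g, plateau %.2e\n",
              x$state$time, max(x$vol_error), x$plateau))
  invisible(x)
}
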