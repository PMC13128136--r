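# Scenario presets reproducing the model's computational experiments.

.pf_cache <- new.env(parent = emptyenv())

#' Available scenario presets
#'
#' * `baseline_chem` - geometry-shaped chemoattractant, chemotaxis force.
#' * `baseline_tim` - same landscape, TIM force.
#' * `uniform_c` - spatially uniform chemoattractant + TIM (control: no
#'   gradient, no net displacement).
#' * `shallow_chem` / `shallow_tim` - source reduced to `shallow_factor`,
#'   comparing stalling chemotaxis against completing TIM migration.
#' * `dorsal_turn` - analytic two-cue landscape + TIM; the cluster crosses
#'   the chamber and then turns dorsally along the oocyte face.
#' @export
scenario_names <- function() {
  c("baseline_chem", "baseline_tim", "uniform_c",
    "shallow_chem", "shallow_tim", "dorsal_turn")
}

#' Drop cached equilibria
#' @export
clear_equilibrium_cache <- function() {
  rm(list = ls(.pf_cache), envir = .pf_cache)
  invisible(NULL)
}

equilibrium_key <- function(M, roster, tables, shape, config) {
  config_hash(list(M = M, roster = roster,
                   tables = unclass(tables), shape = unclass(shape),
                   dt = config$dt, mu = config$mu,
                   t_equilibrate = config$t_equilibrate))
}

#' Equilibrated default scene (cached)
#'
#' Builds the default chamber at resolution `M`, relaxes it force-free to
#' the configured equilibration time, and memoizes the result (in memory,
#' and optionally on disk under `cache_dir`) keyed by a hash of the
#' generating configuration.
#'
#' @param M grid resolution.
#' @param config [sim_config()].
#' @param roster,tables,shape scene ingredients.
#' @param cache logical; reuse a cached equilibrium if available.
#' @param cache_dir optional directory for on-disk reuse across sessions.
#' @return a `pf_equilibration`.
#' @export
equilibrium_scene <- function(M = 99, config = sim_config(),
                              roster = default_roster(),
                              tables = interaction_tables(),
                              shape = chamber_shape(),
                              cache = TRUE, cache_dir = NULL) {
  key <- equilibrium_key(M, roster, tables, shape, config)
  if (cache && !is.null(.pf_cache[[key]])) return(.pf_cache[[key]])
  if (cache && !is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("equilibrium-", key, ".rds"))
    if (file.exists(f)) {
      eq <- readRDS(f)
      .pf_cache[[key]] <- eq
      return(eq)
    }
  }
  grid <- build_grid(M)
  state <- init_state(grid, roster, tables, shape, init_scale = 0.55)
  eq <- equilibrate(state, config, grow_time = min(600, config$t_equilibrate / 2))
  if (cache) .pf_cache[[key]] <- eq
  if (cache && !is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(eq, file.path(cache_dir, paste0("equilibrium-", key, ".rds")))
  }
  eq
}

scenario_chemo <- function(name, grid, geom, shallow_factor, uniform_value) {
  base <- function() extend_to_2d(solve_steady_1d(geom, 4096), grid, "clamp",
                                  smooth = 0.12)
  switch(name,
         baseline_chem = ,
         baseline_tim = base(),
         shallow_chem = ,
         shallow_tim = scale_profile(base(), shallow_factor, geom),
         uniform_c = uniform_field(grid, uniform_value),
         dorsal_turn = analytic_dorsal_field(grid),
         stop("unknown scenario preset: ", name))
}

# migration windows and TIM strengths per preset; the analytic dorsal
# landscape saturates the receptor along the whole path, so that preset's
# traction strength is chosen to match the baseline's mid-path traction
# (mubar * rho products comparable)
scenario_defaults <- function(name) {
  switch(name,
         uniform_c = list(t_migrate = 2000, mubar_c = 0.02),
         dorsal_turn = list(t_migrate = 4000, mubar_c = 0.008),
         shallow_chem = ,
         shallow_tim = list(t_migrate = 2500, mubar_c = 0.02),
         list(t_migrate = 4000, mubar_c = 0.02))
}

#' Run a named scenario
#'
#' Equilibrates (or reuses a cached equilibrium of) the default scene, then
#' switches on the scenario's chemoattractant landscape and guidance force
#' and integrates the migration phase.
#'
#' @param name one of [scenario_names()].
#' @param M grid resolution. The default 99 (`h = 0.05`) is the reference
#'   resolution; coarser grids under-resolve the cluster interface, which
#'   then pins to the lattice and stalls migration.
#' @param config [sim_config()]; `t_migrate` defaults to the preset's
#'   window when left at `NA`.
#' @param fp [force_params()] override; the preset picks the mode and a
#'   preset-appropriate TIM strength, this overrides both.
#' @param rp [receptor_params()].
#' @param geom [channel_geometry()] for the geometry-shaped landscapes.
#' @param shallow_factor source-scaling factor of the shallow scenarios
#'   (default 0.1: an order-of-magnitude weaker source).
#' @param uniform_value concentration of the uniform control field.
#' @param roster,tables,shape scene ingredients.
#' @param cache,cache_dir equilibrium reuse (see [equilibrium_scene()]).
#' @return object of class `pf_run`: `scenario`, final `state`, migration
#'   trajectory `traj`, `chemo`, `fp`, `config`, `equil`, `overshoot`.
#' @export
run_scenario <- function(name, M = 99, config = sim_config(t_migrate = NA),
                         fp = NULL, rp = receptor_params(),
                         geom = channel_geometry(),
                         shallow_factor = 0.1, uniform_value = 1,
                         roster = default_roster(),
                         tables = interaction_tables(),
                         shape = chamber_shape(),
                         cache = TRUE, cache_dir = NULL) {
  name <- match.arg(name, scenario_names())
  defaults <- scenario_defaults(name)
  mode <- if (grepl("chem$", name)) "chem" else "tim"
  if (is.null(fp)) fp <- force_params(mode, mubar_c = defaults$mubar_c)
  else fp$mode <- mode
  if (is.na(config$t_migrate)) config$t_migrate <- defaults$t_migrate
  eq <- equilibrium_scene(M, config, roster, tables, shape, cache, cache_dir)
  chemo <- scenario_chemo(name, eq$state$grid, geom, shallow_factor,
                          uniform_value)
  res <- run_interval(eq$state, config, eq$state$time + config$t_migrate,
                      chemo = chemo, rp = rp, fp = fp)
  structure(list(scenario = name, state = res$state, traj = res$traj,
                 chemo = chemo, fp = fp, rp = rp, config = config,
                 equil = eq, overshoot = res$overshoot, ok = res$ok),
            class = "pf_run")
}

#' @export
print.pf_run <- function(x, ...) {
  n <- nrow(x$traj)
  cat(sprintf("<pf_run> %s: t %g -> %g, centroid (%.2f, %.2f) -> (%.2f, %.2f)\n",
              x$scenario, x$traj$t[1], x$traj$t[n],
              x$traj$x_c[1], x$traj$y_c[1], x$traj$x_c[n], x$traj$y_c[n]))
  at <- arrival_time(x)
  cat(if (is.na(at)) "  no oocyte contact\n"
      else sprintf("  oocyte contact at t = %g\n", at))
  invisible(x)
}
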