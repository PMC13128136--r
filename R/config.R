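# Structured-text configuration: schema, defaults, validation, hashing.

#' Full default configuration
#'
#' Every model parameter with its default, as a nested list mirroring the
#' YAML schema. An empty config file yields exactly this set.
#'
#' @export
default_config <- function() {
  list(
    grid = list(M = 99L, extent = c(0, 5, 0, 5)),
    chamber = list(x1 = 1.85, x2 = 3.15, R = 1.75, y_mid = 2.5),
    cells = default_roster(),
    tables = list(beta0 = 0.9, gamma0 = 1e-4, alpha0 = 0.02, barrier = 300,
                  beta = default_beta(), gamma = default_gamma()),
    run = list(dt = 0.05, mu = 0.05, t_equilibrate = 2000,
               t_migrate = 4000, cadence = 10, seed = 1L),
    force = list(mode = "none", mu_c = 0.045, mubar_c = 0.02,
                 substrate = c("nurse", "oocyte"),
                 perp_sign = 1, sgn_width = 0, support_floor = 0.01),
    chemo = list(provenance = "geometry", D = 1, k = 1, c_posterior = 2,
                 scale_factor = 1, uniform_value = 1,
                 ap_rate = 1.5, dorsal_amp = 1e-4),
    receptor = list(s = 1, Gamma = 0.01, ell = 0.05))
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.data.frame(defaults[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

#' Load and validate a configuration file
#'
#' Reads a YAML config, fills every missing entry from [default_config()],
#' rejects unknown keys (typo safety), and cross-checks physics: the time
#' step must satisfy the stability limit, and a geometry chemoattractant
#' outside the intended receptor regime triggers a warning, as do negative
#' exclusion intensities.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated nested config list (class `pf_file_config`).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.null(user$cells)) {
      user$cells <- do.call(rbind, lapply(user$cells, as.data.frame))
      cfg$cells <- cfg$cells[0, ]   # replace, don't merge row-wise
    }
    for (tb in c("beta", "gamma"))
      if (!is.null(user$tables[[tb]]))
        user$tables[[tb]] <- as_type_matrix(do.call(rbind, user$tables[[tb]]), tb)
    cfg <- merge_config(cfg, user)
  }
  eps2_min <- min(ifelse(cfg$cells$type == "cluster", 5e-4, 1e-3))
  h <- (cfg$grid$extent[2] - cfg$grid$extent[1]) / (cfg$grid$M + 1)
  lim <- stability_limit(h, cfg$run$mu, eps2_min)
  if (cfg$run$dt > lim)
    stop(sprintf("dt = %g violates the stability limit %g at M = %d",
                 cfg$run$dt, lim, cfg$grid$M))
  if (any(cfg$tables$beta < 0) || cfg$tables$beta0 < 0)
    warning("negative exclusion intensity: overlap becomes attractive")
  if (cfg$chemo$provenance == "geometry") {
    geom <- channel_geometry(D = cfg$chemo$D, k = cfg$chemo$k,
                             c_posterior = cfg$chemo$c_posterior)
    pr <- solve_steady_1d(geom, 2048)
    grid <- build_grid(cfg$grid$M, extent = cfg$grid$extent)
    reg <- check_receptor_regime(extend_to_2d(pr, grid, "clamp"),
                                 receptor_params(cfg$receptor$s,
                                                 cfg$receptor$Gamma,
                                                 cfg$receptor$ell))
    if (!reg$ok)
      warning("chemoattractant field violates the receptor operating regime")
  }
  class(cfg) <- c("pf_file_config", "list")
  cfg
}

#' Build simulation objects from a validated config
#'
#' @param cfg result of [load_config()].
#' @return list with `grid`, `state`, `chemo`, `rp`, `fp`, `config`.
#' @export
build_from_config <- function(cfg) {
  grid <- build_grid(cfg$grid$M, extent = cfg$grid$extent)
  shape <- chamber_shape(cfg$chamber$x1, cfg$chamber$x2, cfg$chamber$R,
                         cfg$chamber$y_mid)
  tables <- interaction_tables(cfg$tables$beta0, cfg$tables$beta,
                               cfg$tables$gamma0, cfg$tables$gamma,
                               cfg$tables$alpha0, cfg$tables$barrier)
  state <- init_state(grid, cfg$cells, tables, shape)
  config <- sim_config(cfg$run$dt, cfg$run$mu, cfg$run$t_equilibrate,
                       cfg$run$t_migrate, cfg$run$cadence, cfg$run$seed)
  rp <- receptor_params(cfg$receptor$s, cfg$receptor$Gamma, cfg$receptor$ell)
  fp <- force_params(cfg$force$mode, cfg$force$mu_c, cfg$force$mubar_c,
                     cfg$force$substrate, cfg$force$perp_sign,
                     cfg$force$sgn_width, cfg$force$support_floor)
  chemo <- switch(cfg$chemo$provenance,
    geometry = {
      geom <- channel_geometry(D = cfg$chemo$D, k = cfg$chemo$k,
                               c_posterior = cfg$chemo$c_posterior)
      ch <- extend_to_2d(solve_steady_1d(geom, 4096), grid, "clamp",
                         smooth = 0.12)
      if (cfg$chemo$scale_factor < 1)
        ch <- scale_profile(ch, cfg$chemo$scale_factor, geom)
      ch
    },
    analytic_dorsal = analytic_dorsal_field(grid, cfg$chemo$ap_rate,
                                            cfg$chemo$dorsal_amp),
    uniform = uniform_field(grid, cfg$chemo$uniform_value),
    stop("unknown chemo provenance: ", cfg$chemo$provenance))
  list(grid = grid, state = state, chemo = chemo, rp = rp, fp = fp,
       config = config)
}

canonicalize <- function(x) {
  if (is.environment(x)) stop("cannot canonicalize an environment")
  if (is.function(x)) return(paste(deparse(x), collapse = "\n"))
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    return(lapply(x, canonicalize))
  }
  x
}

#' Stable hash of a configuration
#'
#' Canonicalizes (sorts names recursively, serializes to JSON with full
#' precision) and MD5-hashes. Idempotent and platform-stable for identical
#' configurations.
#'
#' @param x any JSON-serializable configuration object.
#' @export
config_hash <- function(x) {
  js <- jsonlite::toJSON(canonicalize(unclass(x)), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Run manifest
#'
#' Inventory of a run's outputs: config hash, package version, seed,
#' scenario and emitted files.
#'
#' @param config configuration object (hashed).
#' @param scenario scenario name.
#' @param seed integer seed.
#' @param files character vector of output paths.
#' @export
run_manifest <- function(config, scenario, seed, files) {
  structure(list(config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("borderfield")),
                 seed = as.integer(seed),
                 scenario = scenario,
                 files = as.character(files)),
            class = "pf_manifest")
}

#' Write a manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
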