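# Steady chemoattractant landscapes and receptor activation.

#' Extracellular channel geometry for the 1D chemoattractant balance
#'
#' The chemoattractant diffuses and degrades in the mediolateral space
#' between nurse cells, of half-width `r(x)` (cross-section `A(x) = 2 r(x)`).
#' It enters at the posterior (oocyte) end as a fixed concentration and
#' satisfies zero flux at the anterior end. Local widenings of the channel
#' (at points where several cells meet) dilute the signal and flatten the
#' gradient there.
#'
#' @param r function of `x` returning the positive half-width; the default
#'   is a narrow channel with two widened junctions along the path.
#' @param D diffusivity (model units).
#' @param k first-order degradation rate. The default contrast
#'   `cosh(sqrt(k/D) * L) ~ 30` keeps receptor activation negligible at the
#'   anterior while saturated at the source.
#' @param c_posterior fixed concentration at the posterior end (the anterior
#'   face of the oocyte, where the ligand is secreted).
#' @param x_range interval spanned by the migration path; it ends at the
#'   oocyte's anterior face, not at the domain edge.
#' @export
channel_geometry <- function(r = default_channel_radius,
                             D = 1, k = 1, c_posterior = 2,
                             x_range = c(0, 3.2)) {
  stopifnot(is.function(r), D > 0, k >= 0, c_posterior >= 0,
            length(x_range) == 2, x_range[2] > x_range[1])
  structure(list(r = r, D = D, k = k, c_posterior = c_posterior,
                 x_range = x_range),
            class = "pf_channel")
}

#' Default channel half-width profile
#'
#' Four features shape the extracellular space along the migration path:
#'
#' * a tight neck at `x ~ 0.5`, where the anterior epithelium and the first
#'   nurse cells meet: the steady flux through it supports a steep
#'   concentration jump, so receptor activation is negligible in the
#'   anterior basal region but substantial where the cluster starts;
#' * widenings (to ~0.2) at the two three-cell junctions of the nurse
#'   roster (`x ~ 1.8` and `2.75`), which locally dilute the signal and
#'   flatten the gradient;
#' * a sigmoidal opening toward the posterior where the channel meets the
#'   oocyte face, keeping the gradient from steepening sharply at the
#'   source (flux balance gives `dc/dx ~ 1/A`), which would otherwise pull
#'   a migrating cluster's leading edge far harder than its rear.
#'
#' @param x positions.
#' @export
default_channel_radius <- function(x) {
  0.1 - (0.1 - 5e-5) * exp(-((x - 0.5) / 0.12)^2) +
    0.12 * (exp(-((x - 1.8) / 0.25)^2) + exp(-((x - 2.75) / 0.25)^2)) +
    0.4 / (1 + exp(-(x - 3.0) / 0.12))
}

#' Solve the steady 1D channel reaction-diffusion balance
#'
#' Solves `D d/dx (A(x) dc/dx) = k A(x) c` with zero flux at the anterior
#' end and `c = c_posterior` at the posterior end, on `n_points` uniformly
#' spaced nodes (conservative second-order finite volumes with face-averaged
#' `A`; tridiagonal solve). For constant `A` the exact solution is
#' `c_L cosh(sqrt(k/D) x) / cosh(sqrt(k/D) L)`, which the tests use as the
#' closed-form oracle.
#'
#' @param geom a [channel_geometry()].
#' @param n_points number of nodes (>= 8).
#' @return data.frame with columns `x`, `c`.
#' @export
solve_steady_1d <- function(geom, n_points = 2048) {
  stopifnot(inherits(geom, "pf_channel"), n_points >= 8)
  x <- seq(geom$x_range[1], geom$x_range[2], length.out = n_points)
  dx <- x[2] - x[1]
  Af <- 2 * geom$r((x[-1] + x[-n_points]) / 2)     # faces i+1/2, length n-1
  An <- 2 * geom$r(x)
  if (any(Af <= 0) || any(An <= 0)) stop("channel cross-section must be positive")
  n <- n_points
  # rows 1..n-1 are balance equations, row n is the Dirichlet condition
  lower <- numeric(n - 1); diagv <- numeric(n); upper <- numeric(n - 1)
  rhs <- numeric(n)
  s <- geom$D / dx^2
  # anterior node: zero-flux face behaves as a mirror
  diagv[1] <- -2 * s * Af[1] - geom$k * An[1]
  upper[1] <- 2 * s * Af[1]
  for (i in 2:(n - 1)) {
    lower[i - 1] <- s * Af[i - 1]
    diagv[i] <- -s * (Af[i - 1] + Af[i]) - geom$k * An[i]
    upper[i] <- s * Af[i]
  }
  diagv[n] <- 1
  lower[n - 1] <- 0
  rhs[n] <- geom$c_posterior
  ct <- thomas_solve(lower, diagv, upper, rhs)
  data.frame(x = x, c = ct)
}

thomas_solve <- function(lower, diagv, upper, rhs) {
  n <- length(diagv)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- rhs[1] / diagv[1]
  for (i in 2:n) {
    m <- diagv[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  out <- numeric(n)
  out[n] <- dp[n]
  for (i in (n - 1):1) out[i] <- dp[i] - cp[i] * out[i + 1]
  out
}

new_chemo <- function(cmat, grid, provenance, params = list(), profile = NULL) {
  stopifnot(all(cmat >= 0))
  structure(list(c = cmat, grid = grid, provenance = provenance,
                 params = params, profile = profile),
            class = "pf_chemo")
}

#' @export
print.pf_chemo <- function(x, ...) {
  cat(sprintf("<pf_chemo> %s field, c in [%.4g, %.4g]\n",
              x$provenance, min(x$c), max(x$c)))
  invisible(x)
}

#' Extend a 1D anterior-posterior profile to the 2D grid
#'
#' `c(x, y) = c_r(x)` for every `y` (linear interpolation between profile
#' samples at the grid's node x-coordinates). With `extrapolate = "clamp"`
#' the profile is continued at its end values outside its x-range — used
#' when the migration-path profile ends at the oocyte face and the
#' concentration plateaus beyond the source.
#'
#' @param profile data.frame with `x`, `c` (e.g. from [solve_steady_1d()]).
#' @param grid target grid.
#' @param extrapolate `"error"` (default, the profile must cover the grid)
#'   or `"clamp"`.
#' @param smooth standard deviation (in x units) of an optional Gaussian
#'   smoothing of the extended profile. A clamped profile has a slope
#'   discontinuity at the source face which would act as a spurious
#'   force-divergence line; smoothing over ~2 mesh cells removes it.
#' @export
extend_to_2d <- function(profile, grid, extrapolate = c("error", "clamp"),
                         smooth = 0) {
  extrapolate <- match.arg(extrapolate)
  rng <- range(profile$x)
  if (extrapolate == "error" &&
      (min(grid$x) < rng[1] - 1e-9 || max(grid$x) > rng[2] + 1e-9))
    stop("profile does not cover the grid x-range")
  ext_opts <- list(extrapolate = extrapolate, smooth = smooth)
  cx <- stats::approx(profile$x, profile$c, xout = grid$x, rule = 2)$y
  if (smooth > 0) {
    # discrete Gaussian kernel, edge-renormalized
    kw <- max(1L, ceiling(3 * smooth / grid$h))
    kern <- stats::dnorm(seq(-kw, kw) * grid$h, sd = smooth)
    n <- length(cx)
    sm <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - kw):min(n, i + kw)
      w <- kern[j - i + kw + 1]
      sm[i] <- sum(w * cx[j]) / sum(w)
    }
    cx <- sm
  }
  new_chemo(matrix(cx, grid$nx, grid$ny), grid, "geometry",
            params = ext_opts, profile = profile)
}

#' Analytic two-cue landscape with a shallow dorsal bias
#'
#' `c(x, y) = cosh(ap_rate * x) + dorsal_amp * cosh(y)`, with `x` measured
#' from the anterior edge and `y` from the ventral edge, so the second term
#' is a monotone dorsal bias. The steep anterior-posterior term drives
#' transit through the nurse cell matrix; the small-amplitude dorsal term
#' only becomes directionally decisive at the oocyte surface, where the
#' interface tangent turns perpendicular to the A-P axis.
#'
#' @param grid grid.
#' @param ap_rate growth rate of the A-P term (default 1.5).
#' @param dorsal_amp amplitude of the dorsal term (default 1e-4).
#' @export
analytic_dorsal_field <- function(grid, ap_rate = 1.5, dorsal_amp = 1e-4) {
  cm <- eval_on_grid(grid, function(x, y) cosh(ap_rate * x) + dorsal_amp * cosh(y))
  new_chemo(cm, grid, "analytic_dorsal",
            params = list(ap_rate = ap_rate, dorsal_amp = dorsal_amp))
}

#' Spatially uniform control field
#' @param grid grid.
#' @param value constant concentration.
#' @export
uniform_field <- function(grid, value = 1) {
  new_chemo(matrix(value, grid$nx, grid$ny), grid, "uniform",
            params = list(value = value))
}

#' Weaken the chemoattractant source
#'
#' For a geometry-derived field the posterior boundary concentration is
#' scaled and the steady profile re-solved (the balance is linear, so this
#' scales the field pointwise while preserving the anterior-posterior bias);
#' other provenances are scaled pointwise.
#'
#' @param field a `pf_chemo`.
#' @param factor in (0, 1].
#' @param geom the [channel_geometry()] that generated a geometry field.
#' @export
scale_profile <- function(field, factor, geom = NULL) {
  stopifnot(inherits(field, "pf_chemo"), factor > 0, factor <= 1)
  if (field$provenance == "geometry" && !is.null(geom)) {
    geom$c_posterior <- geom$c_posterior * factor
    pr <- solve_steady_1d(geom, n_points = nrow(field$profile))
    out <- extend_to_2d(pr, field$grid,
                        extrapolate = field$params$extrapolate %||% "error",
                        smooth = field$params$smooth %||% 0)
    out$provenance <- "scaled"
    out$params <- c(out$params, list(factor = factor))
    return(out)
  }
  out <- field
  out$c <- field$c * factor
  out$provenance <- "scaled"
  out$params <- c(field$params, list(factor = factor))
  if (!is.null(out$profile)) out$profile$c <- out$profile$c * factor
  out
}

#' Receptor parameters for the saturating activation function
#'
#' @param s maximal activation level.
#' @param Gamma,ell sensitivity constants (defaults 0.01 and 0.05).
#' @export
receptor_params <- function(s = 1, Gamma = 0.01, ell = 0.05) {
  stopifnot(s > 0, Gamma > 0, ell > 0)
  structure(list(s = s, Gamma = Gamma, ell = ell), class = "pf_receptor")
}

#' Saturating receptor activation
#'
#' `rho(c) = s c^3 / ((c^2 + Gamma) (c + ell))`: negligible at basal
#' concentrations, steeply increasing over the transition range, and
#' saturating to `s` at high concentration. Effective cooperativity of
#' order three; the saturation is what makes TIM traction insensitive to
#' gradient magnitude.
#'
#' @param c concentrations (vector or matrix, all >= 0).
#' @param p a [receptor_params()].
#' @export
receptor_activation <- function(c, p = receptor_params()) {
  if (any(c < 0)) stop("negative concentration")
  p$s * c^3 / ((c^2 + p$Gamma) * (c + p$ell))
}

#' Check a field against the intended receptor operating regime
#'
#' The activation should be negligible at anterior basal concentrations,
#' increase along the path, and saturate posteriorly. Reports activation at
#' the field minimum, at mid-path, and at the maximum; flags configurations
#' outside the regime.
#'
#' @param field a `pf_chemo`.
#' @param p a [receptor_params()].
#' @param anterior_max anterior activation must be below `anterior_max * s`.
#' @param posterior_min posterior activation must exceed `posterior_min * s`.
#' @return list with `rho_anterior`, `rho_mid`, `rho_posterior`, logical
#'   flags, and overall `ok`.
#' @export
check_receptor_regime <- function(field, p = receptor_params(),
                                  anterior_max = 0.1, posterior_min = 0.8) {
  g <- field$grid
  cmin <- min(field$c)
  cmax <- max(field$c)
  cmid <- field$c[ceiling(g$nx / 2), ceiling(g$ny / 2)]
  ra <- receptor_activation(cmin, p)
  rm_ <- receptor_activation(cmid, p)
  rp <- receptor_activation(cmax, p)
  anterior_ok <- ra < anterior_max * p$s
  posterior_ok <- rp > posterior_min * p$s
  increasing_ok <- (rp - ra) > 1e-6 * p$s
  list(rho_anterior = ra, rho_mid = rm_, rho_posterior = rp,
       anterior_ok = anterior_ok, posterior_ok = posterior_ok,
       increasing_ok = increasing_ok,
       ok = anterior_ok && posterior_ok && increasing_ok)
}
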