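# Trajectory metrics: centroid path, speed, overlap, arrival, displacement.

#' Indicator-weighted centroid of a phase field
#'
#' @param phi field matrix.
#' @param grid grid.
#' @return numeric `c(x, y)`.
#' @export
centroid <- function(phi, grid) {
  w <- interp_h(phi)
  tot <- sum(w)
  if (tot <= 0) stop("vanished field: centroid undefined")
  c(x = sum(w * grid$x) / tot,
    y = sum(sweep(w, 2, grid$y, `*`)) / tot)
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  out <- stats::filter(x, rep(1 / window, window), sides = 2)
  out <- as.numeric(out)
  # shrink the window near the ends instead of dropping samples
  half <- floor(window / 2)
  for (i in seq_len(min(half, n))) {
    out[i] <- mean(x[1:min(n, i + half)])
    out[n + 1 - i] <- mean(x[max(1, n - i + 1 - half):n])
  }
  out
}

#' Cluster speed along the trajectory
#'
#' Centered finite differences of the centroid arc position over time, with
#' optional moving-average smoothing. The anterior-posterior component
#' (`speed_ap`, signed x-velocity) is reported alongside the full 2D path
#' speed.
#'
#' @param traj trajectory data.frame with `t`, `x_c`, `y_c`.
#' @param window moving-average window in samples (default 5; 1 disables).
#' @return `traj` with `speed` and `speed_ap` columns added.
#' @export
speed_series <- function(traj, window = 5) {
  stopifnot(nrow(traj) >= 2, all(diff(traj$t) > 0))
  n <- nrow(traj)
  seg <- sqrt(diff(traj$x_c)^2 + diff(traj$y_c)^2)
  arc <- c(0, cumsum(seg))
  cd <- function(p) {
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) / (traj$t[2] - traj$t[1])
    v[n] <- (p[n] - p[n - 1]) / (traj$t[n] - traj$t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      v[i] <- (p[i + 1] - p[i - 1]) / (traj$t[i + 1] - traj$t[i - 1])
    }
    v
  }
  traj$speed <- moving_average(cd(arc), window)
  traj$speed_ap <- moving_average(cd(traj$x_c), window)
  traj
}

#' Pairwise overlap field of the dynamic cells
#'
#' `sum_{i<j} phi_i phi_j` (each unordered pair once): highlights the thin
#' interfacial network where cells are in contact and where TIM traction
#' can act.
#'
#' @param state a [pf_state()].
#' @export
overlap_field <- function(state) {
  N <- dim(state$phi)[3]
  out <- matrix(0, state$grid$nx, state$grid$ny)
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    out <- out + state$phi[, , i] * state$phi[, , j]
  out
}

#' Time of cluster-oocyte contact
#'
#' First trajectory time at which the cluster-oocyte overlap integral
#' exceeds `threshold`; `NA` if it never does. For a scenario run the
#' threshold defaults to 5% of the cluster's target volume, which makes the
#' detection resolution-independent.
#'
#' @param x trajectory data.frame (column `ov_oocyte`) or a `pf_run`.
#' @param threshold absolute overlap threshold (data.frame method).
#' @param frac fraction of cluster target volume (`pf_run` method).
#' @param ... unused.
#' @export
arrival_time <- function(x, ...) UseMethod("arrival_time")

#' @rdname arrival_time
#' @export
arrival_time.data.frame <- function(x, threshold, ...) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  hit <- which(x$ov_oocyte > threshold)
  if (length(hit) == 0) NA_real_ else x$t[hit[1]]
}

#' @rdname arrival_time
#' @export
arrival_time.pf_run <- function(x, frac = 0.05, ...) {
  Vbar_c <- x$state$params[[x$state$cluster]]$Vbar
  arrival_time(x$traj, threshold = frac * Vbar_c)
}

#' Net centroid displacement over a trajectory
#'
#' Euclidean distance between the first and last recorded centroid.
#'
#' @param traj trajectory data.frame (or `pf_run`).
#' @export
net_displacement <- function(traj) {
  if (inherits(traj, "pf_run")) traj <- traj$traj
  n <- nrow(traj)
  sqrt((traj$x_c[n] - traj$x_c[1])^2 + (traj$y_c[n] - traj$y_c[1])^2)
}

#' Count local speed maxima
#'
#' Local maxima of a (smoothed) speed series whose topographic prominence
#' (height above the highest saddle separating the peak from higher ground)
#' exceeds `min_prominence` times the series range.
#'
#' @param speed numeric series.
#' @param min_prominence relative prominence threshold (default 0.05).
#' @export
count_speed_peaks <- function(speed, min_prominence = 0.05) {
  n <- length(speed)
  if (n < 3) return(0L)
  rng <- diff(range(speed))
  if (rng <= 0) return(0L)
  peaks <- 0L
  for (i in 2:(n - 1)) {
    if (speed[i] > speed[i - 1] && speed[i] >= speed[i + 1]) {
      # walk outward until strictly higher ground; track the deepest valley
      lmin <- speed[i]
      for (j in seq(i - 1, 1)) {
        if (speed[j] > speed[i]) break
        lmin <- min(lmin, speed[j])
      }
      rmin <- speed[i]
      for (j in seq(i + 1, n)) {
        if (speed[j] > speed[i]) break
        rmin <- min(rmin, speed[j])
      }
      prom <- speed[i] - max(lmin, rmin)
      if (prom > min_prominence * rng) peaks <- peaks + 1L
    }
  }
  peaks
}

#' Two-run comparison summary
#'
#' @param run1,run2 `pf_run` objects.
#' @param frac arrival threshold as a fraction of cluster target volume.
#' @return data.frame with one row per run: arrival time, peak speed, final
#'   position, net displacement.
#' @export
compare_runs <- function(run1, run2, frac = 0.05) {
  row <- function(r) {
    tr <- speed_series(r$traj)
    data.frame(scenario = r$scenario,
               arrival = arrival_time(r, frac = frac),
               peak_speed = max(tr$speed),
               final_x = tr$x_c[nrow(tr)],
               final_y = tr$y_c[nrow(tr)],
               net_displacement = net_displacement(tr))
  }
  rbind(row(run1), row(run2))
}
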