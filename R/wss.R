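# Wall shear rate / wall shear stress estimation.
#
# Two regimes mirror the two blood models:
#   * two-phase (wild type): red blood cells tracked as tracers; for each
#     cell passing near the wall, shear rate is the tangential velocity
#     divided by the distance to the wall (linear near-wall profile).
#   * one-phase (no red blood cells): flow rate from the rate of change of
#     ventricular volume, wall shear from a parabolic profile across the
#     maximum inscribed circle of the lumen cross-section, which gives a
#     conservative maximum: gamma_wall = 4 |Q| / (pi r^3).
# In both, stress = viscosity x shear rate.

# unit conversions: Q in nl/s -> um^3/s; tau in Pa from mPa s * 1/s
NL_TO_UM3 <- 1e6
MPAS_TO_PAS <- 1e-3

#' Poiseuille wall shear rate
#'
#' `4 Q / (pi r^3)` in a coherent unit system (e.g. Q in um^3/s and r in um
#' gives 1/s).  The unit bookkeeping for nl/s and um inputs is done by
#' [parabolic_wall_shear()].
#'
#' @param Q flow rate.
#' @param r tube radius.
#' @return wall shear rate.
#' @export
poiseuille_wall_shear <- function(Q, r) 4 * Q / (pi * r^3)

#' Construct a shear trace
#'
#' A `shear_trace` holds per-frame wall shear rate and the matching wall
#' shear stress `tau = mu * gamma` (Pa, with `mu` in mPa s), plus the
#' provenance of the estimate.  Aggregates (max, 95th percentile, mean) are
#' computed by [summary.shear_trace()] so they are always recomputable from
#' the samples.
#'
#' @param time sample times (s).
#' @param shear_rate wall shear rate (1/s); may contain `NA` for frames
#'   without a qualifying observation.
#' @param viscosity dynamic viscosity (mPa s).
#' @param method provenance tag, e.g. `"two_phase"` or `"one_phase"`.
#' @param extra optional data.frame of additional per-frame columns.
#' @return object of class `shear_trace`.
#' @export
shear_trace <- function(time, shear_rate, viscosity,
                        method = c("two_phase", "one_phase", "other"),
                        extra = NULL) {
  method <- match.arg(method)
  stopifnot(length(time) == length(shear_rate), viscosity > 0)
  samples <- data.frame(time = time, shear_rate = shear_rate,
                        shear_stress = viscosity * MPAS_TO_PAS * shear_rate)
  if (!is.null(extra)) samples <- cbind(samples, extra)
  structure(list(samples = samples, viscosity = viscosity, method = method),
            class = "shear_trace")
}

#' @export
print.shear_trace <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("shear_trace (%s): %d frames, viscosity %.3g mPa s\n",
              x$method, nrow(x$samples), x$viscosity))
  cat(sprintf("  max stress %.4g Pa, 95th percentile %.4g Pa, %d missing frame(s)\n",
              s$max_stress, s$p95_stress, s$n_missing))
  invisible(x)
}

#' Summarize a shear trace
#'
#' @param object a [shear_trace()].
#' @param ... unused.
#' @return list with `max_rate`, `p95_rate`, `mean_rate`, `max_stress`,
#'   `p95_stress`, `mean_stress`, `n`, `n_missing`, `viscosity`, `method`.
#' @export
summary.shear_trace <- function(object, ...) {
  g <- object$samples$shear_rate
  tau <- object$samples$shear_stress
  list(max_rate = max(g, na.rm = TRUE),
       p95_rate = stats::quantile(g, 0.95, na.rm = TRUE, names = FALSE),
       mean_rate = mean(g, na.rm = TRUE),
       max_stress = max(tau, na.rm = TRUE),
       p95_stress = stats::quantile(tau, 0.95, na.rm = TRUE, names = FALSE),
       mean_stress = mean(tau, na.rm = TRUE),
       n = length(g), n_missing = sum(is.na(g)),
       viscosity = object$viscosity, method = object$method)
}

#' @export
as.data.frame.shear_trace <- function(x, ...) x$samples

#' @export
plot.shear_trace <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$time, s$shear_stress, type = "l", xlab = "time (s)",
                 ylab = "wall shear stress (Pa)",
                 main = sprintf("Wall shear stress (%s)", x$method), ...)
  graphics::grid()
  invisible(x)
}

# wall motion at the nearest contour point, by finite difference of the
# matching polyline vertex positions between frames k and k+1
wall_point_velocity <- function(wall, k, polyline_id, seg, t_par) {
  if (k >= length(wall$times)) return(c(0, 0))
  p0 <- wall$contours[[k]][[polyline_id]]
  p1 <- wall$contours[[k + 1]][[polyline_id]]
  if (!all(dim(p0) == dim(p1))) return(c(0, 0))
  dt <- wall$times[k + 1] - wall$times[k]
  a <- (p1[seg, ] - p0[seg, ]) / dt
  b <- (p1[seg + 1, ] - p0[seg + 1, ]) / dt
  (1 - t_par) * a + t_par * b
}

#' Near-wall shear from tracked particles (two-phase regime)
#'
#' For every particle velocity sample within `near_wall_cutoff` of the wall,
#' the wall shear rate is estimated with a linear flow profile between the
#' particle and the wall surface: `gamma = |v_t| / d`, where `d` is the
#' distance to the nearest wall point and `v_t` the component of the
#' (optionally wall-relative) particle velocity tangential to the wall at
#' that point.  The per-frame value is the maximum over qualifying particles
#' (the mean and the count are carried alongside); frames with no qualifying
#' particle are marked missing (`NA`), never zero.
#'
#' @param tracks data.frame with columns `frame`, `particle_id`, `x_um`,
#'   `y_um` and optionally `vx_um_s`, `vy_um_s`.  When velocity columns are
#'   absent, forward differences of consecutive observations of the same
#'   particle are used.
#' @param wall a [wall_geometry()] sharing the track time base (frame `k`
#'   maps to `wall$times[k]`).
#' @param viscosity dynamic viscosity (mPa s).
#' @param near_wall_cutoff qualifying distance (um): a scalar, a per-frame
#'   vector, or `NULL` to use `0.15 * wall$lumen_radius` (the default keeps
#'   the linear-profile Taylor error below about 15%).
#' @param projection `"tangential"` (default; shear is defined by the
#'   tangential velocity gradient) or `"magnitude"`.
#' @param wall_relative subtract the local wall velocity before projecting
#'   (default `TRUE`; the wall moves during the cardiac cycle).
#' @return a [shear_trace()] with extra per-frame columns `n_particles` and
#'   `mean_rate`.
#' @export
near_wall_shear <- function(tracks, wall, viscosity, near_wall_cutoff = NULL,
                            projection = c("tangential", "magnitude"),
                            wall_relative = TRUE) {
  projection <- match.arg(projection)
  stopifnot(inherits(wall, "wall_geometry"))
  n_frames <- length(wall$times)
  if (is.null(near_wall_cutoff)) {
    if (is.null(wall$lumen_radius)) {
      stop("near_wall_cutoff is required when the wall geometry carries no lumen radius")
    }
    cutoff <- 0.15 * wall$lumen_radius
  } else {
    if (any(near_wall_cutoff <= 0)) stop("near_wall_cutoff must be > 0")
    cutoff <- rep_len(near_wall_cutoff, n_frames)
  }

  if (!all(c("vx_um_s", "vy_um_s") %in% names(tracks))) {
    tracks <- derive_track_velocities(tracks, wall$times)
  }
  tracks <- tracks[!is.na(tracks$vx_um_s) & !is.na(tracks$vy_um_s), ]

  rate_max <- rep(NA_real_, n_frames)
  rate_mean <- rep(NA_real_, n_frames)
  n_part <- integer(n_frames)
  for (k in seq_len(n_frames)) {
    tk <- tracks[tracks$frame == k, ]
    if (nrow(tk) == 0) next
    pts <- cbind(tk$x_um, tk$y_um)
    best <- NULL
    for (pl in seq_along(wall$contours[[k]])) {
      nn <- nearest_on_polyline(pts, wall$contours[[k]][[pl]])
      if (is.null(best)) {
        best <- nn
        best$polyline <- rep(pl, nrow(pts))
      } else {
        closer <- nn$distance < best$distance
        best$distance[closer] <- nn$distance[closer]
        best$point[closer, ] <- nn$point[closer, , drop = FALSE]
        best$tangent[closer, ] <- nn$tangent[closer, , drop = FALSE]
        best$segment[closer] <- nn$segment[closer]
        best$t[closer] <- nn$t[closer]
        best$polyline[closer] <- pl
      }
    }
    if (any(best$distance == 0)) stop("particle located exactly on the wall (d = 0)")
    qual <- which(best$distance <= cutoff[k])
    n_part[k] <- length(qual)
    if (length(qual) == 0) next
    rates <- vapply(qual, function(i) {
      v <- c(tk$vx_um_s[i], tk$vy_um_s[i])
      if (wall_relative) {
        v <- v - wall_point_velocity(wall, k, best$polyline[i],
                                     best$segment[i], best$t[i])
      }
      vt <- if (projection == "tangential") {
        abs(sum(v * best$tangent[i, ]))
      } else sqrt(sum(v^2))
      vt / best$distance[i]
    }, numeric(1))
    rate_max[k] <- max(rates)
    rate_mean[k] <- mean(rates)
  }
  if (all(is.na(rate_max))) {
    stop("no particle ever qualified as near-wall; increase the cutoff")
  }
  shear_trace(wall$times, rate_max, viscosity, method = "two_phase",
              extra = data.frame(n_particles = n_part, mean_rate = rate_mean))
}

# forward-difference velocities for consecutive-frame observations
derive_track_velocities <- function(tracks, times) {
  tracks <- tracks[order(tracks$particle_id, tracks$frame), ]
  tracks$vx_um_s <- NA_real_
  tracks$vy_um_s <- NA_real_
  same <- with(tracks, c(particle_id[-1] == particle_id[-nrow(tracks)] &
                           frame[-1] == frame[-nrow(tracks)] + 1, FALSE))
  idx <- which(same)
  dt <- times[tracks$frame[idx] + 1] - times[tracks$frame[idx]]
  tracks$vx_um_s[idx] <- (tracks$x_um[idx + 1] - tracks$x_um[idx]) / dt
  tracks$vy_um_s[idx] <- (tracks$y_um[idx + 1] - tracks$y_um[idx]) / dt
  tracks
}

#' Flow rate from a ventricular volume trace
#'
#' `Q(t) = -dV/dt` by second-order central differences (one-sided at the
#' ends); positive Q is outflow from the ventricle.
#'
#' @param trace data.frame with columns `t_s` and `volume_nl` (>= 3 rows).
#' @return data.frame with columns `t_s` and `Q_nl_s`.
#' @export
flow_rate_from_volume <- function(trace) {
  t <- trace$t_s; v <- trace$volume_nl
  n <- length(t)
  if (n < 3) stop("at least 3 samples are required")
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  dv <- numeric(n)
  dv[1] <- (v[2] - v[1]) / (t[2] - t[1])
  dv[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  data.frame(t_s = t, Q_nl_s = -dv)
}

#' Parabolic-profile wall shear (one-phase regime)
#'
#' `gamma_wall(t) = 4 |Q(t)| / (pi r(t)^3)` with Q in nl/s and r in um
#' (converted internally to 1/s), and `tau = mu * gamma` in Pa.  Used with
#' the inscribed-circle radius of the lumen cross-section this gives a
#' conservative maximum wall shear rate.
#'
#' @param Q data.frame `t_s, Q_nl_s` (as from [flow_rate_from_volume()]) or
#'   a numeric vector (then supply `time`).
#' @param radius per-frame inscribed radius (um); scalar or vector matching Q.
#' @param viscosity dynamic viscosity (mPa s).
#' @param time sample times (s) when `Q` is a bare vector.
#' @return a [shear_trace()] with method `"one_phase"`.
#' @export
parabolic_wall_shear <- function(Q, radius, viscosity, time = NULL) {
  if (is.data.frame(Q)) {
    time <- Q$t_s
    Q <- Q$Q_nl_s
  }
  if (is.null(time)) time <- seq_along(Q) - 1
  radius <- rep_len(radius, length(Q))
  if (any(radius <= 0)) stop("radius must be > 0")
  rate <- poiseuille_wall_shear(abs(Q) * NL_TO_UM3, radius)
  shear_trace(time, rate, viscosity, method = "one_phase")
}

#' Align and smooth a periodic shear trace
#'
#' Circularly shifts the trace so that a reference event lands at
#' `align_at`, then applies a centered moving mean over
#' `2 * envelope_halfwidth + 1` frames with periodic boundary conditions
#' (the smoothing therefore conserves the trace mean).  Aggregates of the
#' returned trace are those of the smoothed series.
#'
#' @param trace a [shear_trace()]; missing frames are filled by periodic
#'   linear interpolation before smoothing (`na_action = "interpolate"`) or
#'   rejected (`"error"`).
#' @param align_at target time (s) for the reference event; `NULL` for no
#'   shift.
#' @param event_time current time (s) of the reference event (e.g. when the
#'   lumen is widest); defaults to the time of the trace maximum.
#' @param envelope_halfwidth smoothing half-width in frames (>= 0);
#'   default 2, i.e. an envelope of +/-2 frames.
#' @param na_action how to treat missing frames.
#' @return a new [shear_trace()] whose samples are the smoothed series.
#' @export
postprocess_trace <- function(trace, align_at = NULL, event_time = NULL,
                              envelope_halfwidth = 2,
                              na_action = c("interpolate", "error")) {
  stopifnot(inherits(trace, "shear_trace"), envelope_halfwidth >= 0)
  na_action <- match.arg(na_action)
  s <- trace$samples
  g <- s$shear_rate
  n <- length(g)
  if (anyNA(g)) {
    if (na_action == "error") stop("trace contains missing frames")
    ok <- which(!is.na(g))
    if (length(ok) < 2) stop("too few observed frames to interpolate")
    # periodic linear interpolation over the cycle
    idx <- seq_len(n)
    ext_i <- c(ok - n, ok, ok + n)
    ext_g <- rep(g[ok], 3)
    g <- stats::approx(ext_i, ext_g, xout = idx)$y
  }
  if (!is.null(align_at)) {
    dt <- if (n > 1) (s$time[n] - s$time[1]) / (n - 1) else 1
    if (is.null(event_time)) event_time <- s$time[which.max(g)]
    shift <- round((align_at - event_time) / dt) %% n
    g <- g[((seq_len(n) - 1 - shift) %% n) + 1]
  }
  if (envelope_halfwidth > 0) {
    w <- 2 * envelope_halfwidth + 1
    g <- as.numeric(stats::filter(g, rep(1 / w, w), sides = 2, circular = TRUE))
  }
  shear_trace(s$time, g, trace$viscosity, method = trace$method)
}

#' Compare two shear traces
#'
#' Fold-change summary between two traces aligned to a common cycle base:
#' ratios of maxima and of 95th percentiles (rate and stress), plus the
#' pointwise stress ratio series.  Zero denominators yield missing markers,
#' never infinities.
#'
#' @param a,b [shear_trace()] objects with equal frame counts.
#' @return object of class `shear_comparison`: list with `max_rate_ratio`,
#'   `p95_rate_ratio`, `max_stress_ratio`, `p95_stress_ratio`, and
#'   `pointwise` (data.frame `time, rate_ratio, stress_ratio`).
#' @export
compare_traces <- function(a, b) {
  stopifnot(inherits(a, "shear_trace"), inherits(b, "shear_trace"))
  if (nrow(a$samples) != nrow(b$samples)) {
    stop("traces must share a common cycle base (equal frame counts)")
  }
  sa <- summary(a); sb <- summary(b)
  safe_ratio <- function(x, y) ifelse(is.na(y) | y == 0, NA_real_, x / y)
  structure(list(
    max_rate_ratio = safe_ratio(sa$max_rate, sb$max_rate),
    p95_rate_ratio = safe_ratio(sa$p95_rate, sb$p95_rate),
    max_stress_ratio = safe_ratio(sa$max_stress, sb$max_stress),
    p95_stress_ratio = safe_ratio(sa$p95_stress, sb$p95_stress),
    pointwise = data.frame(
      time = a$samples$time,
      rate_ratio = safe_ratio(a$samples$shear_rate, b$samples$shear_rate),
      stress_ratio = safe_ratio(a$samples$shear_stress, b$samples$shear_stress))
  ), class = "shear_comparison")
}

#' @export
print.shear_comparison <- function(x, ...) {
  cat("shear trace comparison (a / b)\n")
  cat(sprintf("  max stress ratio:  %.4g\n", x$max_stress_ratio))
  cat(sprintf("  p95 stress ratio:  %.4g\n", x$p95_stress_ratio))
  cat(sprintf("  max rate ratio:    %.4g\n", x$max_rate_ratio))
  invisible(x)
}

#' Ventricular volume from per-slice lumen polygons
#'
#' Disk-summation alternative to a direct volume trace: the volume at one
#' time point is the sum of slice polygon areas times the slice spacing.
#'
#' @param slices list of two-column polygon vertex matrices (um).
#' @param slice_spacing spacing between slices (um).
#' @return volume in nl.
#' @export
volume_from_slices <- function(slices, slice_spacing) {
  areas <- vapply(slices, function(p) {
    p <- as_vertex_matrix(p)
    abs(pracma::polyarea(p[, 1], p[, 2]))
  }, numeric(1))
  sum(areas) * slice_spacing / NL_TO_UM3
}
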