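# Synthetic-data generators with analytic ground truth.
#
# These stand in for the in vivo movies: a contracting 2D tube with parabolic
# (Poiseuille) luminal flow advecting finite-size tracers, a periodic
# ventricular volume trace, single-molecule spot images over a uniform
# background, and two-channel membrane images with controllable apical/basal
# and interface contrasts.  Every generator is a pure function of its
# parameters and a single integer seed.

#' Wall geometry container
#'
#' Per-frame wall contours of a vessel, with optional lumen cross-section
#' polygons and per-frame inscribed radii.
#'
#' @param times strictly increasing frame times (s).
#' @param contours list (one element per frame) of lists of polyline vertex
#'   matrices (microns); each polyline needs at least two vertices.
#' @param cross_sections optional list of closed cross-section polygons
#'   (microns, vertices not repeated), one per frame.
#' @param lumen_radius optional numeric vector of per-frame lumen radii
#'   (microns), used to derive default near-wall cutoffs.
#' @return object of class `wall_geometry`.
#' @export
wall_geometry <- function(times, contours, cross_sections = NULL,
                          lumen_radius = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(contours) != length(times)) {
    stop("one contour set per frame is required")
  }
  for (fr in contours) {
    for (p in fr) if (nrow(p) < 2) stop("polylines need >= 2 vertices")
  }
  structure(list(times = times, contours = contours,
                 cross_sections = cross_sections,
                 lumen_radius = lumen_radius),
            class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf("wall_geometry: %d frames, %d contour polyline(s) per frame%s\n",
              length(x$times), length(x$contours[[1]]),
              if (is.null(x$cross_sections)) "" else ", with cross-sections"))
  invisible(x)
}

#' Pulsatile-tube flow scenario
#'
#' Defines the synthetic beating-vessel scenario: a straight 2D tube of
#' (possibly time-varying) radius around a centerline segment, carrying
#' Poiseuille flow `v(r, t) = 2 Q(t) / (pi R(t)^2) (1 - r^2 / R(t)^2)` whose
#' flow rate is sinusoidal, `Q(t) = peak_flow sin(2 pi t / period)`, unless a
#' custom `flow_fn` is supplied.  Defaults describe an embryonic
#' atrioventricular canal scale scenario: radius 25 um, peak flow 1 nl/s
#' (peak axial velocity about 1 mm/s), cardiac period 0.5 s sampled at 100
#' frames per cycle, 150 tracers of 2 um radius.
#'
#' @param radius lumen radius (um): a constant or a function of time.
#' @param centerline 2 x 2 matrix, rows = segment endpoints (um).
#' @param peak_flow peak flow rate Q0 (nl/s).
#' @param period cardiac period (s).
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames (>= 2).
#' @param viscosity dynamic viscosity (mPa s).
#' @param tracer_count number of advected tracers.
#' @param tracer_radius tracer radius (um); must fit inside the lumen.
#' @param noise_sd additive Gaussian image noise (intensity units, images
#'   are rendered on a 0-1 scale).
#' @param um_per_px pixel calibration (um per pixel).
#' @param rest_volume ventricular rest volume V0 (nl) for the associated
#'   volume trace; must exceed the stroke amplitude `peak_flow * period / (2 pi)`.
#' @param flow_fn optional custom flow-rate function of time (nl/s);
#'   overrides the sinusoidal default.
#' @param seed integer seed.
#' @return object of class `tube_flow_scenario`.
#' @export
tube_flow_scenario <- function(radius = 25,
                               centerline = rbind(c(10, 32), c(130, 32)),
                               peak_flow = 1, period = 0.5,
                               frame_interval = 0.005, n_frames = 200,
                               viscosity = 1.5, tracer_count = 150,
                               tracer_radius = 2, noise_sd = 0.02,
                               um_per_px = 1, rest_volume = 0.3,
                               flow_fn = NULL, seed = 1) {
  radius_fn <- if (is.function(radius)) radius else function(t) rep(radius, length(t))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  times <- (seq_len(n_frames) - 1) * frame_interval
  rr <- radius_fn(times)
  if (any(rr <= 0)) stop("radius must be positive at all sampled times")
  if (tracer_radius >= min(rr)) {
    stop("tracer_radius must be smaller than the minimum lumen radius")
  }
  if (is.null(flow_fn)) {
    if (peak_flow * period / (2 * pi) >= rest_volume) {
      stop("stroke amplitude peak_flow * period / (2 pi) must be below rest_volume")
    }
    flow_fn <- function(t) peak_flow * sin(2 * pi * t / period)
  }
  structure(list(radius_fn = radius_fn, centerline = centerline,
                 peak_flow = peak_flow, period = period,
                 frame_interval = frame_interval, n_frames = n_frames,
                 viscosity = viscosity, tracer_count = tracer_count,
                 tracer_radius = tracer_radius, noise_sd = noise_sd,
                 um_per_px = um_per_px, rest_volume = rest_volume,
                 flow_fn = flow_fn, times = times, seed = seed),
            class = "tube_flow_scenario")
}

# numeric derivative of the radius function
radius_rate <- function(radius_fn, t, h = 1e-6) {
  (radius_fn(t + h) - radius_fn(t - h)) / (2 * h)
}

#' Generate a synthetic tube movie with analytic ground truth
#'
#' Advects `tracer_count` tracers with the Poiseuille profile of the
#' scenario.  Each tracer keeps a fixed relative radial position
#' `rho = r / R(t)` (so radial motion follows the moving wall) and moves
#' axially with `v(rho, t) = 2 Q(t) / (pi R(t)^2) (1 - rho^2)`, wrapping
#' periodically at the ends of the centerline so the tracer count is
#' conserved.  The returned ground truth carries each tracer's exact
#' velocity and the analytic wall shear rate `4 |Q(t)| / (pi R(t)^3)`
#' (converted to 1/s from nl/s and um).  Images render tracers as Gaussian
#' blobs plus the wall as bright contour lines, with additive Gaussian
#' noise; identical seeds give bit-identical output.
#'
#' @param scenario a [tube_flow_scenario()].
#' @param render_images logical; set `FALSE` to skip image rendering when
#'   only geometry/track/volume ground truth is needed.
#' @return list with `images` (list of matrices, values on a 0-1 scale
#'   before clamping, or `NULL`), `wall` ([wall_geometry()]), `tracks`
#'   (data.frame `frame, particle_id, x_um, y_um, vx_um_s, vy_um_s`),
#'   `volume` (data.frame `t_s, volume_nl`), `shear_gt` (data.frame
#'   `t_s, Q_nl_s, radius_um, shear_rate_s`), and `scenario`.
#' @export
generate_tube_movie <- function(scenario, render_images = TRUE) {
  stopifnot(inherits(scenario, "tube_flow_scenario"))
  sc <- scenario
  times <- sc$times
  nT <- sc$n_frames
  R <- sc$radius_fn(times)
  Q <- sc$flow_fn(times)

  c0 <- sc$centerline[1, ]; c1 <- sc$centerline[2, ]
  axis_vec <- c1 - c0
  L <- sqrt(sum(axis_vec^2))
  u <- axis_vec / L             # unit axial direction
  nvec <- c(-u[2], u[1])        # unit normal

  # fixed relative radial positions; tracers must fit inside the lumen
  rho_max <- 1 - sc$tracer_radius / min(R)
  state <- with_seed(sc$seed, list(
    rho = stats::runif(sc$tracer_count, -rho_max, rho_max),
    s0 = stats::runif(sc$tracer_count, 0, L)
  ))
  rho <- state$rho

  axial_speed <- function(t) { # per-tracer axial velocity at time t (um/s)
    2 * sc$flow_fn(t) * 1e6 / (pi * sc$radius_fn(t)^2) * (1 - rho^2)
  }

  # integrate axial positions with midpoint substeps
  s <- matrix(NA_real_, nT, sc$tracer_count)
  s[1, ] <- state$s0
  nsub <- 8L
  for (k in seq_len(nT - 1)) {
    cur <- s[k, ]
    h <- sc$frame_interval / nsub
    t0 <- times[k]
    for (j in seq_len(nsub)) {
      cur <- cur + h * axial_speed(t0 + (j - 0.5) * h)
    }
    s[k + 1, ] <- cur %% L
  }
  s <- s %% L

  Rdot <- radius_rate(sc$radius_fn, times)
  tracks <- do.call(rbind, lapply(seq_len(nT), function(k) {
    pos_x <- c0[1] + u[1] * s[k, ] + nvec[1] * rho * R[k]
    pos_y <- c0[2] + u[2] * s[k, ] + nvec[2] * rho * R[k]
    v_ax <- 2 * Q[k] * 1e6 / (pi * R[k]^2) * (1 - rho^2)
    v_rad <- rho * Rdot[k]
    data.frame(frame = k, particle_id = seq_len(sc$tracer_count),
               x_um = pos_x, y_um = pos_y,
               vx_um_s = u[1] * v_ax + nvec[1] * v_rad,
               vy_um_s = u[2] * v_ax + nvec[2] * v_rad)
  }))

  # wall contours: two polylines per frame (upper and lower wall)
  n_wall_pts <- 33
  sgrid <- seq(0, L, length.out = n_wall_pts)
  contours <- lapply(seq_len(nT), function(k) {
    top <- cbind(c0[1] + u[1] * sgrid + nvec[1] * R[k],
                 c0[2] + u[2] * sgrid + nvec[2] * R[k])
    bot <- cbind(c0[1] + u[1] * sgrid - nvec[1] * R[k],
                 c0[2] + u[2] * sgrid - nvec[2] * R[k])
    list(top, bot)
  })
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  cross_sections <- lapply(seq_len(nT), function(k) {
    cbind(R[k] * cos(theta), R[k] * sin(theta))
  })
  wall <- wall_geometry(times, contours, cross_sections, lumen_radius = R)

  # ventricular volume trace consistent with Q = -dV/dt
  stroke <- function(t) { # integral of Q from 0 to t (nl)
    vapply(t, function(ti) {
      stats::integrate(sc$flow_fn, 0, ti, rel.tol = 1e-10,
                       subdivisions = 400L)$value
    }, numeric(1))
  }
  volume <- data.frame(t_s = times, volume_nl = sc$rest_volume - stroke(times))
  if (any(volume$volume_nl <= 0)) stop("rest_volume too small: volume trace non-positive")

  shear_gt <- data.frame(t_s = times, Q_nl_s = Q, radius_um = R,
                         shear_rate_s = 4 * abs(Q) * 1e6 / (pi * R^3))

  images <- NULL
  if (render_images) {
    images <- with_seed(sc$seed + 1L, {
      render_tube_frames(sc, tracks, contours)
    })
  }

  list(images = images, wall = wall, tracks = tracks, volume = volume,
       shear_gt = shear_gt, scenario = sc)
}

# Render all frames: wall contour lines, Gaussian tracer blobs, noise.
render_tube_frames <- function(sc, tracks, contours) {
  extent <- apply(do.call(rbind, contours[[1]]), 2, range)
  W <- ceiling((max(extent[2, 1], max(tracks$x_um)) + 10) / sc$um_per_px)
  H <- ceiling((max(extent[2, 2], max(tracks$y_um)) + 10) / sc$um_per_px)
  sigma_px <- sc$tracer_radius / sc$um_per_px
  lapply(seq_len(sc$n_frames), function(k) {
    img <- matrix(0.1, H, W)
    for (p in contours[[k]]) {
      img <- draw_polyline(img, p / sc$um_per_px, value = 0.8, width = 1.5)
    }
    tk <- tracks[tracks$frame == k, ]
    img <- add_gaussian_blobs(img, tk$x_um / sc$um_per_px,
                              tk$y_um / sc$um_per_px,
                              amplitude = 0.6, sigma = sigma_px)
    if (sc$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, sc$noise_sd), H, W)
    }
    img
  })
}

# Set pixels within `width` px of a polyline to `value`.
draw_polyline <- function(img, polyline, value, width = 1) {
  xr <- range(polyline[, 1]); yr <- range(polyline[, 2])
  cols <- max(1L, floor(xr[1] - width)):min(ncol(img), ceiling(xr[2] + width) + 1L)
  rows <- max(1L, floor(yr[1] - width)):min(nrow(img), ceiling(yr[2] + width) + 1L)
  grid <- cbind(rep(cols - 1, each = length(rows)), rep(rows - 1, times = length(cols)))
  d <- nearest_on_polyline(grid, polyline)$distance
  hit <- d <= width
  img[cbind(rep(rows, times = length(cols))[hit],
            rep(cols, each = length(rows))[hit])] <- value
  img
}

# Additively render Gaussian blobs at (x, y) pixel coordinates.
add_gaussian_blobs <- function(img, x, y, amplitude, sigma) {
  half <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    c0 <- max(1L, floor(x[i]) - half + 1L); c1 <- min(ncol(img), ceiling(x[i]) + half + 1L)
    r0 <- max(1L, floor(y[i]) - half + 1L); r1 <- min(nrow(img), ceiling(y[i]) + half + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    gx <- exp(-(xs - x[i])^2 / (2 * sigma^2))
    gy <- exp(-(ys - y[i])^2 / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * outer(gy, gx)
  }
  img
}

#' Generate a sinusoidal ventricular volume trace
#'
#' `V(t) = V0 + A sin(2 pi t / period)` sampled every `dt`, with the
#' closed-form flow rate `Q(t) = -dV/dt = -A (2 pi / period) cos(2 pi t / period)`
#' returned as ground truth (positive Q = outflow).
#'
#' @param V0 rest volume (nl).
#' @param amplitude oscillation amplitude A (nl); must satisfy `A < V0`.
#' @param period period (s).
#' @param dt sampling interval (s).
#' @param n number of samples.
#' @return list with `trace` (data.frame `t_s, volume_nl`) and `Q_true`
#'   (data.frame `t_s, Q_nl_s`).
#' @export
generate_volume_trace <- function(V0, amplitude, period, dt, n) {
  if (amplitude >= V0) stop("amplitude must be smaller than V0")
  t <- (seq_len(n) - 1) * dt
  omega <- 2 * pi / period
  list(
    trace = data.frame(t_s = t, volume_nl = V0 + amplitude * sin(omega * t)),
    Q_true = data.frame(t_s = t, Q_nl_s = -amplitude * omega * cos(omega * t))
  )
}

#' Spot-image specification
#'
#' @param image_shape integer `c(nrow, ncol)` in pixels.
#' @param background_level uniform background intensity (>= 0).
#' @param dot_counts named integer vector: dots to plant per region label.
#' @param dot_amplitude peak dot intensity above background.
#' @param dot_sigma Gaussian dot width (px).
#' @param roi_polygons named list of two-column vertex matrices (px), one per
#'   region label in `dot_counts` (extra background-only regions allowed).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return object of class `spot_image_spec`.
#' @export
spot_image_spec <- function(image_shape, background_level, dot_counts,
                            dot_amplitude, dot_sigma, roi_polygons,
                            noise_sd = 0, seed = 1) {
  if (background_level < 0) stop("background_level must be >= 0")
  if (is.null(names(roi_polygons)) || any(names(roi_polygons) == "")) {
    stop("roi_polygons must be a named list")
  }
  if (!all(names(dot_counts) %in% names(roi_polygons))) {
    stop("every dot_counts label needs a matching ROI polygon")
  }
  structure(list(image_shape = image_shape,
                 background_level = background_level,
                 dot_counts = dot_counts, dot_amplitude = dot_amplitude,
                 dot_sigma = dot_sigma, roi_polygons = roi_polygons,
                 noise_sd = noise_sd, seed = seed),
            class = "spot_image_spec")
}

#' Generate a synthetic single-molecule spot image
#'
#' Renders a uniform background plus isolated Gaussian dots planted inside
#' their assigned ROI polygons (fully inside: at least `3 dot_sigma` from
#' the boundary) with a minimum mutual separation of `6 dot_sigma` so that
#' reference dots are isolated.  Placement is by bounded rejection sampling;
#' exceeding the retry budget is an error.  The ground-truth ledger records
#' each dot's analytic integrated intensity above background
#' (`intensity = amplitude * 2 pi sigma^2`), the raw integrated intensity a
#' measurement over the dot's effective area would return
#' (`intensity_raw = intensity + background_level * area`; this is what a
#' dot calibration expects), and the effective area (`pi (3 sigma)^2`).
#'
#' @param spec a [spot_image_spec()].
#' @param max_tries rejection-sampling budget per dot.
#' @return list with `image`, `rois` (the labeled polygons), and `ledger`
#'   (data.frame `region, dot_id, x, y, intensity, area`).
#' @export
generate_spot_image <- function(spec, max_tries = 5000) {
  stopifnot(inherits(spec, "spot_image_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  sigma <- spec$dot_sigma
  margin <- 3 * sigma
  min_sep <- 6 * sigma
  ledger <- with_seed(spec$seed, {
    rows <- list()
    placed <- matrix(numeric(0), ncol = 2)
    for (lab in names(spec$dot_counts)) {
      n_dots <- spec$dot_counts[[lab]]
      if (n_dots == 0) next
      poly <- as_vertex_matrix(spec$roi_polygons[[lab]])
      xr <- range(poly[, 1]); yr <- range(poly[, 2])
      for (d in seq_len(n_dots)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
          if (!point_in_polygon(cand[1], cand[2], poly)) next
          if (dist_to_polygon_boundary(rbind(cand), poly) < margin) next
          if (nrow(placed) > 0 &&
              min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)) < min_sep) next
          ok <- TRUE
          break
        }
        if (!ok) stop(sprintf("could not place an isolated dot in region '%s' after %d tries", lab, max_tries))
        placed <- rbind(placed, cand)
        area <- pi * (3 * sigma)^2
        net <- spec$dot_amplitude * 2 * pi * sigma^2
        rows[[length(rows) + 1]] <- data.frame(
          region = lab, dot_id = length(rows) + 1L,
          x = cand[1], y = cand[2],
          intensity = net,
          intensity_raw = net + spec$background_level * area,
          area = area)
      }
    }
    if (length(rows) == 0) {
      data.frame(region = character(0), dot_id = integer(0), x = numeric(0),
                 y = numeric(0), intensity = numeric(0),
                 intensity_raw = numeric(0), area = numeric(0))
    } else do.call(rbind, rows)
  })
  image <- matrix(spec$background_level, H, W)
  if (nrow(ledger) > 0) {
    image <- add_gaussian_blobs(image, ledger$x, ledger$y,
                                amplitude = spec$dot_amplitude, sigma = sigma)
  }
  if (spec$noise_sd > 0) {
    image <- image + with_seed(spec$seed + 1L,
      matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W))
  }
  list(image = image, rois = spec$roi_polygons, ledger = ledger)
}

#' Generate a two-channel polarity image
#'
#' Renders a row of rectangular cells with annotated apical (top), basal
#' (bottom) and lateral cell-cell interface membrane segments.  Each segment
#' class carries the stated green/red intensities; interface intensities and
#' labels recycle across the interior interfaces.  Membranes are drawn two
#' pixels thick along integer pixel rows/columns so that noise-free bilinear
#' sampling along the annotated segments recovers the planted intensities
#' exactly.  Annotated segments are inset 3 px from cell corners to avoid
#' corner overlap between membrane classes.
#'
#' @param apical_green,basal_green,apical_red,basal_red membrane intensities
#'   (>= 0) of the apical and basal segments in each channel.
#' @param n_cells number of cells in the row.
#' @param cell_w,cell_h cell width and height (px).
#' @param origin top-left corner (x, y) of the first cell (px).
#' @param interface_green,interface_red intensities of the lateral
#'   interfaces, recycled over the `n_cells - 1` interior interfaces.
#' @param interface_labels labels recycled over the interior interfaces.
#' @param noise_sd additive Gaussian noise standard deviation (per channel).
#' @param seed integer seed.
#' @return list with `green`, `red` (matrices) and `segments` (data.frame
#'   `id, side, label, x0, y0, x1, y1` in px; `side` is one of `apical`,
#'   `basal`, `interface`).
#' @export
generate_polarity_image <- function(apical_green, basal_green, apical_red,
                                    basal_red, n_cells = 6, cell_w = 20,
                                    cell_h = 30, origin = c(10, 10),
                                    interface_green = 1, interface_red = 1,
                                    interface_labels = "interface",
                                    noise_sd = 0, seed = 1) {
  vals <- c(apical_green, basal_green, apical_red, basal_red,
            interface_green, interface_red)
  if (any(vals < 0)) stop("intensities must be >= 0")
  x0 <- origin[1]; y_top <- origin[2]; y_bot <- origin[2] + cell_h
  W <- ceiling(x0 + n_cells * cell_w + 10)
  H <- ceiling(y_bot + 10)
  green <- matrix(0, H, W); red <- matrix(0, H, W)

  fill_rect <- function(img, xa, xb, ya, yb, value) {
    img[(ya + 1):(yb + 1), (xa + 1):(xb + 1)] <- value
    img
  }
  n_if <- max(0L, n_cells - 1L)
  if_green <- rep_len(interface_green, n_if)
  if_red <- rep_len(interface_red, n_if)
  if_lab <- rep_len(interface_labels, max(1L, n_if))[seq_len(n_if)]

  # lateral interfaces first; apical/basal bands overwrite the corners
  for (i in seq_len(n_if)) {
    xi <- x0 + i * cell_w
    green <- fill_rect(green, xi, xi + 1, y_top, y_bot, if_green[i])
    red <- fill_rect(red, xi, xi + 1, y_top, y_bot, if_red[i])
  }
  green <- fill_rect(green, x0, x0 + n_cells * cell_w, y_top, y_top + 1, apical_green)
  green <- fill_rect(green, x0, x0 + n_cells * cell_w, y_bot - 1, y_bot, basal_green)
  red <- fill_rect(red, x0, x0 + n_cells * cell_w, y_top, y_top + 1, apical_red)
  red <- fill_rect(red, x0, x0 + n_cells * cell_w, y_bot - 1, y_bot, basal_red)

  segs <- list()
  inset <- 3
  for (i in seq_len(n_cells)) {
    xa <- x0 + (i - 1) * cell_w + inset
    xb <- x0 + i * cell_w - inset
    segs[[length(segs) + 1]] <- data.frame(
      id = sprintf("cell%d_apical", i), side = "apical", label = "apical",
      x0 = xa, y0 = y_top, x1 = xb, y1 = y_top)
    segs[[length(segs) + 1]] <- data.frame(
      id = sprintf("cell%d_basal", i), side = "basal", label = "basal",
      x0 = xa, y0 = y_bot, x1 = xb, y1 = y_bot)
  }
  for (i in seq_len(n_if)) {
    xi <- x0 + i * cell_w
    segs[[length(segs) + 1]] <- data.frame(
      id = sprintf("interface%d", i), side = "interface", label = if_lab[i],
      x0 = xi, y0 = y_top + inset, x1 = xi, y1 = y_bot - inset)
  }
  segments <- do.call(rbind, segs)

  if (noise_sd > 0) {
    noise <- with_seed(seed, list(
      g = matrix(stats::rnorm(H * W, 0, noise_sd), H, W),
      r = matrix(stats::rnorm(H * W, 0, noise_sd), H, W)))
    green <- green + noise$g
    red <- red + noise$r
  }
  list(green = green, red = red, segments = segments)
}
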