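# Particle segmentation and free-form deformation (FFD) registration.
#
# Frame-to-frame motion is estimated by minimizing the mean squared
# intensity difference between a fixed frame and a warped moving frame.  The
# displacement field is parameterized on a regular control grid (default
# spacing 5.6 um) with cubic B-spline interpolation, optimized with L-BFGS-B
# over a 3-level multi-resolution pyramid, warm-started from half the
# previous time step's field to smooth velocity changes across frames.

# cubic B-spline basis weights for fractional offsets t in [0, 1);
# returns an n x 4 matrix for control points i0-1 .. i0+2
bspline_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# sparse design matrix mapping control coefficients (one axis) to dense
# positions; coords are 0-based pixel coordinates, spacing in the same units
bspline_design <- function(coords, spacing, n_ctrl) {
  s <- coords / spacing
  i0 <- pmin(pmax(floor(s), 0), n_ctrl - 4)
  w <- bspline_weights(s - i0)
  n <- length(coords)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = as.integer(i0 + 1 + rep(0:3, each = n)),
    x = as.numeric(w),
    dims = c(n, n_ctrl))
}

n_ctrl_for <- function(extent_px, spacing) floor(extent_px / spacing) + 4L

# block-mean downsample by integer factor (crops any remainder)
downsample <- function(img, f) {
  if (f == 1) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  rs <- rowsum(img, rep(seq_len(nr %/% f), each = f))
  t(rowsum(t(rs), rep(seq_len(nc %/% f), each = f))) / f^2
}

image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]; gx[, nc] <- img[, nc] - img[, nc - 1]
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]; gy[nr, ] <- img[nr, ] - img[nr - 1, ]
  list(gx = gx, gy = gy)
}

#' Pairwise free-form image registration
#'
#' Estimates the control-grid displacement field that minimizes the mean
#' squared intensity difference between `fixed` and the warped `moving`
#' frame, so that `moving(x + u(x)) ~ fixed(x)`: a bright structure at `x`
#' in the fixed frame moved to `x + u(x)` in the moving frame.  The field is
#' cubic-B-spline interpolated from a regular control grid and optimized
#' coarse-to-fine over a multi-resolution pyramid; the objective at the
#' solution never exceeds the objective at the initialization.
#'
#' @param fixed,moving numeric matrices of identical dimension.
#' @param grid_spacing control-grid spacing (um); default 5.6.
#' @param um_per_px pixel calibration.
#' @param init optional [deformation_field] (matching grid) used as warm
#'   start, e.g. half the previous time step's field.
#' @param pyramid_levels number of resolution levels (default 3).
#' @param max_iter L-BFGS-B iteration cap per level.
#' @param rel_tol relative objective-change convergence tolerance.
#' @param smooth_weight optional quadratic penalty on control-grid
#'   displacement differences (default 0: pure mean-square metric, grid
#'   coarseness is the only regularizer).
#' @return object of class `deformation_field`: control coefficients
#'   (displacements in full-resolution px), grid geometry, per-level
#'   objective values, and a `converged` flag (`FALSE` means the iteration
#'   cap was hit and the best-so-far field is returned).
#' @export
register_pair <- function(fixed, moving, grid_spacing = 5.6, um_per_px = 1,
                          init = NULL, pyramid_levels = 3, max_iter = 100,
                          rel_tol = 1e-5, smooth_weight = 0) {
  if (!all(dim(fixed) == dim(moving))) stop("frames must have the same shape")
  nr <- nrow(fixed); nc <- ncol(fixed)
  h <- grid_spacing / um_per_px
  ncx <- n_ctrl_for(nc - 1, h)
  ncy <- n_ctrl_for(nr - 1, h)
  if (!is.null(init)) {
    stopifnot(inherits(init, "deformation_field"))
    if (!all(dim(init$coef_x) == c(ncy, ncx))) {
      stop("init field has a different control grid")
    }
    Cx <- init$coef_x; Cy <- init$coef_y
  } else {
    Cx <- matrix(0, ncy, ncx); Cy <- matrix(0, ncy, ncx)
  }

  objective <- data.frame(level = integer(0), init = numeric(0),
                          final = numeric(0))
  converged <- TRUE
  for (lev in seq(pyramid_levels - 1, 0)) {
    f <- 2^lev
    if (min(nr, nc) %/% f < 8) next # level would be degenerate
    F_l <- downsample(fixed, f)
    M_l <- downsample(moving, f)
    nrl <- nrow(F_l); ncl <- ncol(F_l)
    gr <- image_gradients(M_l)
    # full-resolution coordinates of level-l pixel centers
    xs <- (seq_len(ncl) - 1) * f + (f - 1) / 2
    ys <- (seq_len(nrl) - 1) * f + (f - 1) / 2
    Wx <- bspline_design(xs, h, ncx)
    Wy <- bspline_design(ys, h, ncy)
    WyT <- Matrix::t(Wy)
    base_x <- matrix(rep(seq_len(ncl) - 1, each = nrl), nrl, ncl)
    base_y <- matrix(rep(seq_len(nrl) - 1, times = ncl), nrl, ncl)
    npix <- nrl * ncl

    unpack <- function(par) {
      list(Cx = matrix(par[seq_len(ncy * ncx)], ncy, ncx),
           Cy = matrix(par[ncy * ncx + seq_len(ncy * ncx)], ncy, ncx))
    }
    fn <- function(par) {
      p <- unpack(par)
      Ux <- as.matrix(Wy %*% p$Cx %*% Matrix::t(Wx))
      Uy <- as.matrix(Wy %*% p$Cy %*% Matrix::t(Wx))
      w <- bilinear_sample(M_l, base_x + Ux / f, base_y + Uy / f)
      obj <- mean((w - F_l)^2)
      if (smooth_weight > 0) {
        obj <- obj + smooth_weight *
          (sum(diff(p$Cx)^2) + sum(diff(t(p$Cx))^2) +
             sum(diff(p$Cy)^2) + sum(diff(t(p$Cy))^2)) / (ncy * ncx)
      }
      obj
    }
    grad <- function(par) {
      p <- unpack(par)
      Ux <- as.matrix(Wy %*% p$Cx %*% Matrix::t(Wx))
      Uy <- as.matrix(Wy %*% p$Cy %*% Matrix::t(Wx))
      sx <- base_x + Ux / f; sy <- base_y + Uy / f
      w <- bilinear_sample(M_l, sx, sy)
      diffimg <- matrix(2 * (w - F_l) / npix, nrl, ncl)
      mgx <- matrix(bilinear_sample(gr$gx, sx, sy), nrl, ncl)
      mgy <- matrix(bilinear_sample(gr$gy, sx, sy), nrl, ncl)
      gCx <- as.matrix(WyT %*% (diffimg * mgx / f) %*% Wx)
      gCy <- as.matrix(WyT %*% (diffimg * mgy / f) %*% Wx)
      if (smooth_weight > 0) {
        pen_grad <- function(C) {
          g <- matrix(0, nrow(C), ncol(C))
          d1 <- diff(C); g[-nrow(C), ] <- g[-nrow(C), ] - 2 * d1
          g[-1, ] <- g[-1, ] + 2 * d1
          d2 <- diff(t(C)); gt <- matrix(0, ncol(C), nrow(C))
          gt[-ncol(C), ] <- gt[-ncol(C), ] - 2 * d2
          gt[-1, ] <- gt[-1, ] + 2 * d2
          (g + t(gt)) * smooth_weight / (ncy * ncx)
        }
        gCx <- gCx + pen_grad(p$Cx)
        gCy <- gCy + pen_grad(p$Cy)
      }
      c(as.numeric(gCx), as.numeric(gCy))
    }

    par0 <- c(as.numeric(Cx), as.numeric(Cy))
    obj0 <- fn(par0)
    opt <- stats::optim(par0, fn, grad, method = "L-BFGS-B",
                        control = list(maxit = max_iter,
                                       factr = rel_tol / .Machine$double.eps))
    if (opt$value <= obj0) {
      p <- unpack(opt$par)
      Cx <- p$Cx; Cy <- p$Cy
      obj_final <- opt$value
    } else {
      obj_final <- obj0
    }
    if (opt$convergence == 1) converged <- FALSE
    objective <- rbind(objective,
                       data.frame(level = lev, init = obj0, final = obj_final))
  }

  structure(list(coef_x = Cx, coef_y = Cy, spacing_um = grid_spacing,
                 um_per_px = um_per_px, dim = c(nr, nc),
                 objective = objective, converged = converged),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("deformation_field: %d x %d control grid, spacing %.3g um, %s\n",
              nrow(x$coef_x), ncol(x$coef_x), x$spacing_um,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Evaluate a deformation field at arbitrary points
#'
#' @param object a [deformation_field].
#' @param newdata two-column matrix or data.frame of (x, y) positions in
#'   pixel coordinates.
#' @param units `"px"` (default) or `"um"` for the returned displacements.
#' @param ... unused.
#' @return matrix with columns `ux`, `uy`.
#' @export
predict.deformation_field <- function(object, newdata, units = c("px", "um"),
                                      ...) {
  units <- match.arg(units)
  pts <- as.matrix(newdata)
  h <- object$spacing_um / object$um_per_px
  ncx <- ncol(object$coef_x); ncy <- nrow(object$coef_x)
  n <- nrow(pts)
  sx <- pts[, 1] / h; sy <- pts[, 2] / h
  ix <- pmin(pmax(floor(sx), 0), ncx - 4)
  iy <- pmin(pmax(floor(sy), 0), ncy - 4)
  wxm <- bspline_weights(sx - ix)
  wym <- bspline_weights(sy - iy)
  ux <- numeric(n); uy <- numeric(n)
  for (a in 1:4) {
    for (b in 1:4) {
      idx <- cbind(iy + a, ix + b) # 1-based control indices
      wgt <- wym[, a] * wxm[, b]
      ux <- ux + wgt * object$coef_x[idx]
      uy <- uy + wgt * object$coef_y[idx]
    }
  }
  out <- cbind(ux = ux, uy = uy)
  if (units == "um") out <- out * object$um_per_px
  out
}

#' Warp an image with a deformation field
#'
#' Samples `moving` at `x + u(x)` so that the result is comparable to the
#' fixed frame of the registration that produced the field.
#'
#' @param moving numeric matrix.
#' @param field a [deformation_field].
#' @return warped matrix of the same dimension.
#' @export
warp_image <- function(moving, field) {
  nr <- nrow(moving); nc <- ncol(moving)
  pts <- cbind(rep(seq_len(nc) - 1, each = nr),
               rep(seq_len(nr) - 1, times = nc))
  u <- predict(field, pts)
  matrix(bilinear_sample(moving, pts[, 1] + u[, "ux"], pts[, 2] + u[, "uy"]),
         nr, nc)
}

#' Segment bright particles by thresholding
#'
#' Pixels above the intensity threshold are grouped into connected
#' components; components below the minimum area are discarded as noise.
#'
#' @param image numeric matrix.
#' @param threshold intensity threshold (must lie within the image dynamic
#'   range).
#' @param min_area minimum component area in px^2 (default 4).
#' @param max_area maximum component area in px^2 (default `Inf`); useful to
#'   reject large bright structures such as vessel walls that are not
#'   tracer particles.
#' @param um_per_px pixel calibration for the returned centroids.
#' @return data.frame `id, x_um, y_um, area_px`; zero rows when nothing is
#'   above threshold.
#' @export
segment_particles <- function(image, threshold, min_area = 4, max_area = Inf,
                              um_per_px = 1) {
  mask <- image > threshold
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_px = numeric(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  area <- tabulate(labs)
  keep <- which(area >= min_area & area <= max_area)
  if (length(keep) == 0) return(empty)
  cx <- tapply(idx[, 2] - 1, labs, mean)[as.character(keep)]
  cy <- tapply(idx[, 1] - 1, labs, mean)[as.character(keep)]
  data.frame(id = seq_along(keep),
             x_um = as.numeric(cx) * um_per_px,
             y_um = as.numeric(cy) * um_per_px,
             area_px = area[keep])
}

#' Track particles through a movie by pairwise registration
#'
#' For each consecutive frame pair the deformation field is estimated with
#' [register_pair()], warm-started with half of the previous pair's field.
#' Each segmented particle's velocity is the interpolated displacement at
#' its centroid divided by the frame interval; identities are linked by
#' nearest neighbor between the warped position and the next frame's
#' segmented centroids within a gating radius (gating failures terminate
#' tracks; unmatched detections start new ones).
#'
#' @param stack list of matrices or a 3D array (`[row, col, frame]`).
#' @param threshold segmentation intensity threshold.
#' @param grid_spacing control-grid spacing (um).
#' @param um_per_px pixel calibration.
#' @param frame_interval time between frames (s).
#' @param gating_radius linking radius (um); default `2 * grid_spacing`.
#' @param min_area minimum particle area (px^2).
#' @param max_area maximum particle area (px^2).
#' @param ... further arguments passed to [register_pair()].
#' @return data.frame `frame, particle_id, x_um, y_um, vx_um_s, vy_um_s`
#'   (velocities `NA` on each track's final observation), with the list of
#'   per-pair deformation fields in attribute `"fields"`.
#' @export
track_movie <- function(stack, threshold, grid_spacing = 5.6, um_per_px = 1,
                        frame_interval = 1, gating_radius = 2 * grid_spacing,
                        min_area = 4, max_area = Inf, ...) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  n <- length(stack)
  if (n < 2) stop("at least 2 frames are required")
  seg <- lapply(stack, segment_particles, threshold = threshold,
                min_area = min_area, max_area = max_area,
                um_per_px = um_per_px)
  fields <- vector("list", n - 1)
  prev <- NULL
  rows <- list()
  ids <- seq_len(nrow(seg[[1]]))
  next_id <- length(ids) + 1L
  for (k in seq_len(n - 1)) {
    init <- if (is.null(prev)) NULL else halve_field(prev)
    fld <- register_pair(stack[[k]], stack[[k + 1]],
                         grid_spacing = grid_spacing, um_per_px = um_per_px,
                         init = init, ...)
    fields[[k]] <- fld
    prev <- fld
    sk <- seg[[k]]
    if (nrow(sk) > 0) {
      u <- predict(fld, cbind(sk$x_um, sk$y_um) / um_per_px, units = "um")
      rows[[k]] <- data.frame(frame = k, particle_id = ids,
                              x_um = sk$x_um, y_um = sk$y_um,
                              vx_um_s = u[, "ux"] / frame_interval,
                              vy_um_s = u[, "uy"] / frame_interval)
      warped <- cbind(sk$x_um + u[, "ux"], sk$y_um + u[, "uy"])
    } else {
      rows[[k]] <- NULL
      warped <- matrix(numeric(0), ncol = 2)
    }
    # link to next frame's detections
    sk1 <- seg[[k + 1]]
    new_ids <- rep(NA_integer_, nrow(sk1))
    if (nrow(sk1) > 0 && nrow(warped) > 0) {
      taken <- rep(FALSE, nrow(sk1))
      for (i in seq_len(nrow(warped))) {
        d <- sqrt((sk1$x_um - warped[i, 1])^2 + (sk1$y_um - warped[i, 2])^2)
        d[taken] <- Inf
        j <- which.min(d)
        if (length(j) == 1 && is.finite(d[j]) && d[j] <= gating_radius) {
          new_ids[j] <- ids[i]
          taken[j] <- TRUE
        }
      }
    }
    fresh <- which(is.na(new_ids))
    if (length(fresh) > 0) {
      new_ids[fresh] <- next_id + seq_along(fresh) - 1L
      next_id <- next_id + length(fresh)
    }
    ids <- new_ids
  }
  skn <- seg[[n]]
  if (nrow(skn) > 0) {
    rows[[n]] <- data.frame(frame = n, particle_id = ids,
                            x_um = skn$x_um, y_um = skn$y_um,
                            vx_um_s = NA_real_, vy_um_s = NA_real_)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "fields") <- fields
  out
}

# half of a field's displacement, for warm-starting the next pair
halve_field <- function(field) {
  field$coef_x <- field$coef_x / 2
  field$coef_y <- field$coef_y / 2
  field
}
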