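# Shared planar geometry and image-sampling utilities.
#
# Coordinate convention used throughout the package: pixel-centered, origin at
# the top-left pixel, x increasing to the right (matrix columns), y increasing
# downwards (matrix rows).  The center of matrix element [r, c] sits at
# (x, y) = (c - 1, r - 1) in pixel units; physical coordinates are pixel
# coordinates times a scalar micron-per-pixel calibration.

#' Pixel centers covered by a polygon
#'
#' Returns the matrix indices of all pixels whose *centers* fall inside a
#' polygon, using an even-odd crossing test with the half-open convention:
#' centers on a left/top edge are in, centers on a right/bottom edge are out.
#' The rule is deterministic and additive over polygon tilings, so disjoint
#' regions of interest never double-count a boundary pixel.
#'
#' @param dim integer vector `c(nrow, ncol)` of the image.
#' @param polygon numeric matrix with two columns (x, y) of polygon vertices
#'   in pixel coordinates; the polygon is closed implicitly.
#' @return integer matrix with columns `row`, `col` of covered pixels.
#' @export
pixels_in_polygon <- function(dim, polygon) {
  polygon <- as_vertex_matrix(polygon)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  cols <- max(1L, floor(xr[1]) + 1L):min(dim[2], ceiling(xr[2]) + 1L)
  rows <- max(1L, floor(yr[1]) + 1L):min(dim[1], ceiling(yr[2]) + 1L)
  if (xr[2] < 0 || yr[2] < 0 || xr[1] > dim[2] - 1 || yr[1] > dim[1] - 1) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  grid <- expand.grid(row = rows, col = cols)
  keep <- point_in_polygon(grid$col - 1, grid$row - 1, polygon)
  cbind(row = grid$row[keep], col = grid$col[keep])
}

#' Even-odd point-in-polygon test (half-open rule)
#'
#' @param x,y numeric vectors of query coordinates.
#' @param polygon two-column vertex matrix.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, polygon) {
  polygon <- as_vertex_matrix(polygon)
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- nrow(polygon)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (py[i] > y) != (py[j] > y)
    if (any(crosses)) {
      xint <- (px[j] - px[i]) * (y[crosses] - py[i]) / (py[j] - py[i]) + px[i]
      flip <- x[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

as_vertex_matrix <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3 || anyNA(polygon)) {
    stop("polygon must be a numeric matrix of >= 3 (x, y) vertices")
  }
  storage.mode(polygon) <- "double"
  polygon
}

# Distances from n points to m segments; returns n x m matrix plus, on
# request, the foot point and unit tangent of each segment.
dist_points_segments <- function(pts, segs) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(pts); m <- nrow(segs)
  d <- matrix(NA_real_, n, m)
  for (k in seq_len(m)) {
    ax <- segs[k, 1]; ay <- segs[k, 2]; bx <- segs[k, 3]; by <- segs[k, 4]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      d[, k] <- sqrt((pts[, 1] - ax)^2 + (pts[, 2] - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / len2))
      d[, k] <- sqrt((pts[, 1] - (ax + t * vx))^2 + (pts[, 2] - (ay + t * vy))^2)
    }
  }
  d
}

# Nearest point, distance, tangent and arc parameter on a polyline for each
# query point.  `polyline` is a k x 2 vertex matrix.
nearest_on_polyline <- function(pts, polyline) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  k <- nrow(polyline)
  segs <- cbind(polyline[-k, 1], polyline[-k, 2], polyline[-1, 1], polyline[-1, 2])
  d <- dist_points_segments(pts, segs)
  seg <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_len(nrow(pts)), seg)]
  ax <- segs[seg, 1]; ay <- segs[seg, 2]
  vx <- segs[seg, 3] - ax; vy <- segs[seg, 4] - ay
  len2 <- pmax(vx * vx + vy * vy, .Machine$double.eps)
  t <- pmin(1, pmax(0, ((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / len2))
  len <- sqrt(len2)
  list(
    distance = best,
    point = cbind(ax + t * vx, ay + t * vy),
    tangent = cbind(vx / len, vy / len),
    segment = seg,
    t = t
  )
}

# Distance to the boundary of a closed polygon (vertices not repeated).
dist_to_polygon_boundary <- function(pts, polygon) {
  polygon <- as_vertex_matrix(polygon)
  closed <- rbind(polygon, polygon[1, , drop = FALSE])
  k <- nrow(closed)
  segs <- cbind(closed[-k, 1], closed[-k, 2], closed[-1, 1], closed[-1, 2])
  d <- dist_points_segments(matrix(as.numeric(pts), ncol = 2), segs)
  apply(d, 1, min)
}

#' Maximum inscribed circle of a simple polygon
#'
#' Finds the interior point maximizing the distance to the polygon boundary
#' (the pole of inaccessibility); its distance is the inradius that
#' parameterizes the parabolic flow profile of the one-phase wall-shear model.
#' A regular grid search at the stated resolution seeds a Nelder-Mead
#' refinement of the signed boundary distance, so the returned radius is
#' accurate to well within `resolution / 2`.
#'
#' @param polygon two-column vertex matrix (microns), simple and of positive
#'   area; do not repeat the first vertex.
#' @param resolution grid spacing (microns) of the initial search.
#' @param refine logical; run the local refinement step (default `TRUE`).
#' @return list with `center` (length-2 numeric) and `radius`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' max_inscribed_circle(sq, resolution = 0.05)
#' @export
max_inscribed_circle <- function(polygon, resolution, refine = TRUE) {
  polygon <- as_vertex_matrix(polygon)
  if (resolution <= 0) stop("resolution must be > 0")
  area <- abs(pracma::polyarea(polygon[, 1], polygon[, 2]))
  if (area <= .Machine$double.eps) stop("degenerate polygon: area is zero")
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  xs <- seq(xr[1] + resolution / 2, xr[2] - resolution / 2, by = resolution)
  ys <- seq(yr[1] + resolution / 2, yr[2] - resolution / 2, by = resolution)
  if (length(xs) == 0) xs <- mean(xr)
  if (length(ys) == 0) ys <- mean(yr)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- point_in_polygon(grid[, 1], grid[, 2], polygon)
  if (!any(inside)) stop("no interior grid point found; decrease resolution")
  cand <- grid[inside, , drop = FALSE]
  d <- dist_to_polygon_boundary(cand, polygon)
  best <- which.max(d)
  center <- cand[best, ]
  radius <- d[best]
  if (refine) {
    # shrinking-grid descent: robust on the plateaus of the min-distance
    # surface where simplex methods stall
    step <- resolution
    while (step > 1e-7) {
      offs <- step * c(-1, -0.5, 0, 0.5, 1)
      cand <- cbind(rep(center[1] + offs, times = 5),
                    rep(center[2] + offs, each = 5))
      ok <- point_in_polygon(cand[, 1], cand[, 2], polygon)
      if (any(ok)) {
        cand <- cand[ok, , drop = FALSE]
        d <- dist_to_polygon_boundary(cand, polygon)
        b <- which.max(d)
        if (d[b] > radius) {
          center <- cand[b, ]
          radius <- d[b]
        }
      }
      step <- step / 2
    }
  }
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Bilinear image interpolation
#'
#' Samples an image at fractional pixel coordinates, clamping to the border.
#'
#' @param image numeric matrix.
#' @param x,y coordinates in pixel units (pixel `[r, c]` center is
#'   `(c - 1, r - 1)`).
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- as.numeric(x); y <- as.numeric(y)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  if (nc < 2) x0 <- rep(0, length(x))
  if (nr < 2) y0 <- rep(0, length(y))
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, pmin(x0 + 2, nc))
  i10 <- cbind(pmin(y0 + 2, nr), x0 + 1)
  i11 <- cbind(pmin(y0 + 2, nr), pmin(x0 + 2, nc))
  image[i00] * (1 - fx) * (1 - fy) + image[i01] * fx * (1 - fy) +
    image[i10] * (1 - fx) * fy + image[i11] * fx * fy
}

# Evaluate a seeded expression with a private RNG stream, leaving the global
# .Random.seed untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
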