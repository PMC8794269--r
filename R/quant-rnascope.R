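# Background-corrected dot-density statistic for single-molecule FISH images.
#
# The statistic is an intensity budget, not a spot detector: the integrated
# intensity of a region of interest, corrected by a background level per unit
# area (measured in a signal-free reference region) and divided by the mean
# background-corrected integrated intensity of isolated reference dots:
#
#   background  = intensity(background ROI) / area(background ROI)
#   dot_mean    = (sum_i I_i - background * sum_i a_i) / n   (n reference dots)
#   count(ROI)  = (I_ROI - background * A_ROI) / dot_mean
#   density     = count / A_ROI
#
# Counts close to zero can come out slightly negative through measurement
# error; negative values are passed through unmodified by design.

#' Measure a polygonal region of interest
#'
#' Integrated intensity is the sum of the values of all pixels whose centers
#' fall inside the polygon (half-open boundary rule, see
#' [pixels_in_polygon()]); area is the pixel count.
#'
#' @param image numeric matrix.
#' @param polygon two-column vertex matrix (px).
#' @param label optional region label.
#' @return data.frame of class `roi_measurement` with columns `label`,
#'   `integrated_intensity`, `area_px`.
#' @export
measure_roi <- function(image, polygon, label = NA_character_) {
  px <- pixels_in_polygon(dim(image), polygon)
  if (nrow(px) == 0) stop("polygon does not cover any pixel center of the image")
  out <- data.frame(label = label,
                    integrated_intensity = sum(image[px]),
                    area_px = nrow(px))
  class(out) <- c("roi_measurement", class(out))
  out
}

#' Background intensity per unit area
#'
#' @param background_roi a [measure_roi()] result for a signal-free region
#'   (the atrial region in the original protocol).
#' @return background level (intensity per px^2).
#' @export
background_level <- function(background_roi) {
  if (background_roi$area_px <= 0) stop("background ROI has zero area")
  background_roi$integrated_intensity / background_roi$area_px
}

#' Reference-dot calibration
#'
#' Bundles the per-dot measurements of isolated reference dots (the
#' protocol uses 20; any n >= 1 is accepted and recorded) with the
#' background region measurement.
#'
#' @param dots data.frame with columns `intensity` (integrated intensity)
#'   and `area` (px^2), one row per isolated reference dot.
#' @param background_roi a [measure_roi()] result.
#' @return object of class `dot_calibration`.
#' @export
dot_calibration <- function(dots, background_roi) {
  if (!all(c("intensity", "area") %in% names(dots)) || nrow(dots) < 1) {
    stop("dots must have columns 'intensity' and 'area' and at least one row")
  }
  structure(list(dots = dots, background_roi = background_roi,
                 n_dots = nrow(dots)),
            class = "dot_calibration")
}

#' Mean background-corrected intensity per dot
#'
#' `(sum_i I_i - background * sum_i a_i) / n` over the n reference dots.  A
#' non-positive corrected mean means the reference dots are dimmer than the
#' background, which is a calibration failure and an error.
#'
#' @param cal a [dot_calibration()].
#' @param background optional background level; computed from the
#'   calibration's background ROI when omitted.
#' @return mean integrated intensity per dot.
#' @export
mean_dot_intensity <- function(cal, background = NULL) {
  stopifnot(inherits(cal, "dot_calibration"))
  if (is.null(background)) background <- background_level(cal$background_roi)
  m <- (sum(cal$dots$intensity) - background * sum(cal$dots$area)) / cal$n_dots
  if (m <= 0) {
    stop("calibration failure: reference dots are not brighter than the background")
  }
  m
}

#' Dot count and density in a region of interest
#'
#' `count = (I_ROI - background * A_ROI) / dot_mean`; `density = count / A`.
#' Negative counts (regions slightly dimmer than the background estimate)
#' are returned unmodified.
#'
#' @param roi a [measure_roi()] result.
#' @param background background level (intensity per px^2).
#' @param dot_mean mean intensity per dot (> 0).
#' @param um_per_px optional calibration; when supplied, `density` is per
#'   um^2 instead of per px^2.
#' @return data.frame `label, count, density, area_px`.
#' @export
dots_in_roi <- function(roi, background, dot_mean, um_per_px = NULL) {
  if (dot_mean <= 0) stop("dot_mean must be > 0")
  count <- (roi$integrated_intensity - background * roi$area_px) / dot_mean
  area_unit <- if (is.null(um_per_px)) roi$area_px else roi$area_px * um_per_px^2
  data.frame(label = roi$label, count = count, density = count / area_unit,
             area_px = roi$area_px)
}

#' Quantify dot densities across z-slices
#'
#' Applies the dot statistic to measurements summed over the given z-slices
#' (the protocol uses the mid-valve slice plus its two neighbors, i.e. 3
#' slices; any number is accepted).  Summing, rather than averaging, keeps
#' counts additive: identical slices give exactly `n_slices` times the
#' single-slice count.  Per-slice results are attached so an averaging
#' convention remains recoverable.
#'
#' @param slices list of image matrices (default convention: 3).
#' @param regions named list of region polygons (px), each present in every
#'   slice.
#' @param cal_dots data.frame `intensity, area` of isolated reference dots
#'   (pooled across slices, as measured by the caller or taken from a
#'   generator ledger).
#' @param background_polygon polygon of the signal-free background region.
#' @param um_per_px optional calibration for densities per um^2.
#' @return data.frame `region, count, density, area_px` with attributes
#'   `background`, `dot_mean`, `n_dots`, `per_slice`.
#' @export
quantify_slices <- function(slices, regions, cal_dots, background_polygon,
                            um_per_px = NULL) {
  if (length(regions) == 0) {
    return(data.frame(region = character(0), count = numeric(0),
                      density = numeric(0), area_px = numeric(0)))
  }
  if (is.null(names(regions))) stop("regions must be a named list")
  bg_meas <- lapply(slices, function(img) {
    m <- try(measure_roi(img, background_polygon, label = "background"),
             silent = TRUE)
    if (inherits(m, "try-error")) stop("background region missing from a slice")
    m
  })
  bg_I <- sum(vapply(bg_meas, function(m) m$integrated_intensity, numeric(1)))
  bg_A <- sum(vapply(bg_meas, function(m) m$area_px, numeric(1)))
  background <- bg_I / bg_A
  cal <- dot_calibration(cal_dots,
                         data.frame(label = "background",
                                    integrated_intensity = bg_I, area_px = bg_A))
  dot_mean <- mean_dot_intensity(cal, background = background)

  per_slice <- list()
  out <- lapply(names(regions), function(lab) {
    meas <- lapply(seq_along(slices), function(si) {
      m <- try(measure_roi(slices[[si]], regions[[lab]], label = lab),
               silent = TRUE)
      if (inherits(m, "try-error")) {
        stop(sprintf("region '%s' missing from slice %d", lab, si))
      }
      m
    })
    per_slice[[lab]] <<- do.call(rbind, lapply(seq_along(meas), function(si) {
      cbind(slice = si,
            dots_in_roi(meas[[si]], background, dot_mean, um_per_px))
    }))
    total <- data.frame(label = lab,
                        integrated_intensity = sum(vapply(meas, function(m)
                          m$integrated_intensity, numeric(1))),
                        area_px = sum(vapply(meas, function(m) m$area_px,
                                             numeric(1))))
    d <- dots_in_roi(total, background, dot_mean, um_per_px)
    data.frame(region = lab, count = d$count, density = d$density,
               area_px = d$area_px)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "background") <- background
  attr(res, "dot_mean") <- dot_mean
  attr(res, "n_dots") <- cal$n_dots
  attr(res, "per_slice") <- per_slice
  res
}

#' Flag candidate isolated dots (helper)
#'
#' Convenience helper that flags local maxima well above background and far
#' from any other candidate, as a starting point for choosing reference
#' dots.  Reference-dot selection remains the caller's responsibility; the
#' dot statistic itself never depends on this helper.
#'
#' @param image numeric matrix.
#' @param background background level.
#' @param min_height minimum height above background.
#' @param min_separation minimum distance between candidates (px).
#' @return data.frame `x, y, value`.
#' @export
find_candidate_dots <- function(image, background, min_height,
                                min_separation = 10) {
  nr <- nrow(image); nc <- ncol(image)
  cand <- which(image > background + min_height, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  }
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  sel <- matrix(numeric(0), ncol = 2)
  keep <- integer(0)
  for (i in ord) {
    p <- c(cand[i, 2] - 1, cand[i, 1] - 1)
    if (nrow(sel) == 0 ||
        min(sqrt((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2)) >= min_separation) {
      sel <- rbind(sel, p)
      keep <- c(keep, i)
    }
  }
  data.frame(x = sel[, 1], y = sel[, 2], value = vals[keep])
}
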