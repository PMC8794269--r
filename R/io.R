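# Readers and writers for the package's file formats: multi-page TIFF image
# stacks, CSV tables (tracks, wall contours, volume traces), and JSON
# documents (ROI polygons, fluid configurations).  All CSV files are
# comma-separated UTF-8 with a header row and '.' decimal; coordinates are
# in microns unless a column name says otherwise.

#' Write an image stack as multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` for storage.
#'
#' @param images list of numeric matrices (one per frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(images, path) {
  clamped <- lapply(images, function(im) pmin(pmax(im, 0), 1))
  tiff::writeTIFF(clamped, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#'
#' @param path file path.
#' @return list of numeric matrices.
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) if (length(dim(im)) == 3) im[, , 1] else im)
}

#' Write / read particle tracks CSV
#'
#' Columns: `frame, particle_id, x_um, y_um, vx_um_s, vy_um_s`.
#'
#' @param tracks data.frame of tracks.
#' @param path file path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_tracks_csv <- function(tracks, path) {
  cols <- c("frame", "particle_id", "x_um", "y_um", "vx_um_s", "vy_um_s")
  missing_v <- setdiff(cols, names(tracks))
  for (m in missing_v) tracks[[m]] <- NA_real_
  utils::write.csv(tracks[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) utils::read.csv(path)

#' Write / read wall contours CSV
#'
#' Long format: `frame, polyline_id, vertex_index, x_um, y_um` plus a
#' `t_s` time column.
#'
#' @param wall a [wall_geometry()].
#' @param path file path.
#' @return `path` invisibly (write); a [wall_geometry()] (read; cross
#'   sections and lumen radii are not round-tripped).
#' @export
write_contours_csv <- function(wall, path) {
  rows <- do.call(rbind, lapply(seq_along(wall$times), function(k) {
    do.call(rbind, lapply(seq_along(wall$contours[[k]]), function(pl) {
      p <- wall$contours[[k]][[pl]]
      data.frame(frame = k, t_s = wall$times[k], polyline_id = pl,
                 vertex_index = seq_len(nrow(p)), x_um = p[, 1], y_um = p[, 2])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  d <- utils::read.csv(path)
  frames <- sort(unique(d$frame))
  times <- vapply(frames, function(k) d$t_s[d$frame == k][1], numeric(1))
  contours <- lapply(frames, function(k) {
    dk <- d[d$frame == k, ]
    lapply(sort(unique(dk$polyline_id)), function(pl) {
      dp <- dk[dk$polyline_id == pl, ]
      dp <- dp[order(dp$vertex_index), ]
      cbind(dp$x_um, dp$y_um)
    })
  })
  wall_geometry(times, contours)
}

#' Write / read a ventricular volume trace CSV
#'
#' Columns: `t_s, volume_nl`.
#'
#' @param trace data.frame `t_s, volume_nl`.
#' @param path file path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_volume_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t_s", "volume_nl")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_csv
#' @export
read_volume_csv <- function(path) utils::read.csv(path)

#' Write / read labeled ROI polygons as JSON
#'
#' Stored as a JSON object mapping each region label to an array of
#' `[x, y]` vertex pairs.
#'
#' @param polygons named list of two-column vertex matrices.
#' @param path file path.
#' @return `path` invisibly (write); a named list of matrices (read).
#' @export
write_rois_json <- function(polygons, path) {
  obj <- lapply(polygons, function(p) unname(apply(p, 1, c, simplify = FALSE)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(p) {
    m <- if (is.matrix(p)) p else do.call(rbind, p)
    storage.mode(m) <- "double"
    m
  })
}

#' Write / read a fluid configuration JSON
#'
#' Serializes a [fluid_spec()] or [nanofluid_spec()] losslessly.
#'
#' @param spec the specification object.
#' @param path file path.
#' @return `path` invisibly (write); the reconstructed object (read).
#' @export
write_fluid_json <- function(spec, path) {
  obj <- if (inherits(spec, "nanofluid_spec")) {
    list(type = "nanofluid_spec", d_p = spec$d_p, phi = spec$phi,
         fluid = unclass(spec$fluid))
  } else if (inherits(spec, "fluid_spec")) {
    c(list(type = "fluid_spec"), unclass(spec))
  } else stop("spec must be a fluid_spec or nanofluid_spec")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fluid_json
#' @export
read_fluid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- function(f) fluid_spec(mu_f = f$mu_f, M = f$M, rho_f0 = f$rho_f0,
                               T0 = f$T0)
  if (identical(obj$type, "nanofluid_spec")) {
    nanofluid_spec(fl(obj$fluid), d_p = obj$d_p, phi = obj$phi)
  } else fl(obj)
}

#' Write a shear trace CSV
#'
#' Columns: `time, shear_rate, shear_stress` plus any extra per-frame
#' columns; viscosity and method recorded in a comment-free sidecar is
#' avoided by writing them as constant columns.
#'
#' @param trace a [shear_trace()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_shear_csv <- function(trace, path) {
  d <- trace$samples
  d$viscosity_mPas <- trace$viscosity
  d$method <- trace$method
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shear_csv
#' @export
read_shear_csv <- function(path) {
  d <- utils::read.csv(path)
  shear_trace(d$time, d$shear_rate, viscosity = d$viscosity_mPas[1],
              method = d$method[1])
}
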